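---
title: "Estimating gait speed from a pocket-worn smartphone IMU: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gait speed from a pocket-worn smartphone IMU: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketgait)
```

## The problem

Gait speed is a clinically meaningful vital sign, but accurate measurement
normally needs an instrumented walkway or motion capture. A smartphone
carried in a front pants pocket records tri-axial accelerometer and
gyroscope streams at ~100 Hz, from which spatiotemporal gait parameters
can be estimated with no equipment beyond the phone and one anthropometric
input, the user's leg length. `pocketgait` implements that pipeline, the
multiplicative bias correction that makes it accurate across the step-length
range, the calibration procedure for deriving the correction against a
reference system, and the agreement/reliability statistics used to
validate such devices.

## The inverted-pendulum model

During single support the body vaults over a relatively rigid stance leg of
length $l$: the center of mass travels an arc, rising by
$h = l(1 - \cos\theta_0)$ between foot contact and mid-stance, where
$\theta_0$ is the half-angle swept per step. Geometry then gives the step
length

$$ \mathrm{SL} = 2\sqrt{2hl - h^2}, $$

so one step length requires only $l$ and the per-step vertical excursion
$h$ of a sensor riding near the pelvis. Stride length is the sum of the two
step lengths in a stride, and gait speed is stride length divided by stride
time. `step_length_pendulum()` implements the formula with its exact
identities ($h = 0 \mapsto 0$, $h = l \mapsto 2l$, strictly increasing on
$[0, l]$, homogeneous of degree one in $(h, l)$).

## Signal path

1. **Orientation** (`estimate_orientation`). Only the vertical axis
   matters, so orientation is a tilt estimate: gyroscope integration
   corrected each sample toward the low-passed accelerometer gravity
   direction (complementary filter, gain 0.02 per sample at 100 Hz; the
   accelerometer reference is smoothed with a 0.5 s first-order low-pass).
   Initialization uses the mean accelerometer vector over the first 0.5 s,
   assumed quasi-static because trials start from standing. The
   magnetometer is deliberately unused: heading is irrelevant for vertical
   extraction and indoor magnetic fields are unreliable. A `gyro_only`
   mode dead-reckons from the initial pose for diagnostic use.
2. **Rotation and gravity removal** (`rotate_to_global`). The accelerometer
   vector is rotated into the gravity-aligned frame and $g = 9.80665$
   m/s² is subtracted from the vertical component.
3. **Heel-strike detection** (`detect_heel_strikes`). The vertical
   acceleration peaks when the body vaults onto the new stance leg, with
   impact ringing superimposed. A 4th-order zero-phase low-pass at 3 Hz
   keeps the gait fundamental and first harmonic while collapsing the
   ringing into the single underlying peak. Local maxima are accepted when
   their topographic prominence exceeds
   $k \cdot \max(\mathrm{MAD}, 0.25\,\mathrm{SD})$ of the filtered series
   ($k = 1$ by default), with a 0.4 s refractory period. The MAD makes the
   threshold robust and amplitude-scale invariant; the SD floor covers
   sparse impulse-like series on which the MAD collapses (it is inert on
   dense walking signals, where MAD ≈ SD). Detection uses the
   accelerometer only; with a single pocket sensor, left and right cannot
   be told apart, so foot identity is assigned by alternation and no
   toe-off labelling is attempted.
4. **Stride segmentation** (`segment_strides`). Stride $k$ spans heel
   strikes $k \to k+2$; stride time is the sample count between them over
   the sampling rate. Strides outside 0.5–2.5 s are excluded and counted
   (turn artifacts, missed events).
5. **Vertical position** (`vertical_position`). The vertical acceleration
   is doubly integrated (cumulative trapezoid) and the position series is
   high-pass filtered with a 4th-order zero-lag Butterworth filter at
   0.11 Hz to remove integration drift. Per step, $h$ is the peak-to-trough
   excursion of the filtered position within the step window
   (`step_height`), matching the apex-to-contact pendulum geometry and
   robust to window phase.
6. **Adjustment** (`apply_adjustment`). The raw pendulum estimate carries a
   length-dependent multiplicative bias: short steps are underestimated and
   long steps overestimated. The correction multiplies each raw step length
   by a constant selected by the zone the *raw* estimate falls in. The
   built-in tables (`default_coefficients`) use zones 0.2/0.5/0.8/1.1 m
   with multipliers (1.37, 1.02, 0.74) for all walking, (1.40, 1.04, 0.74)
   for normal walking and (1.36, 1.01, 0.73) for dual-task walking. Zones
   are half-open $[a, b)$ with the last zone closed; out-of-range inputs
   use the nearest zone and are flagged. Adjusted gait speed is recomputed
   from adjusted step lengths, never by scaling speed directly.

## Numerical choices

**Zero-phase filtering.** "Zero-lag" is implemented as forward–backward
application of the designed 4th-order filter, so the effective magnitude
response is the squared single-pass response and events keep their timing.
The implementation uses steady-state initial conditions and odd-reflection
padding whose length covers the filter's actual settling (computed from
the slowest pole's decay to $10^{-6}$). The long padding matters: a
0.11 Hz high-pass settles over tens of seconds, and shorter padding leaks
edge transients into the position series that the step-height readout
would see.

**Integration guards.** Two exactly-null components are removed before the
mandated 0.11 Hz high-pass: the trial-mean acceleration before
integration, and the least-squares linear trend of the raw double
integral. Both lie in the high-pass's DC null space (four zeros at DC), so
removing them changes nothing in the passband; doing it explicitly keeps
their large finite-length edge transients out of the filter. Velocity is
not filtered; only the position series is.

**Stride length from two steps.** Stride length is computed as the sum of
the stride's two step lengths rather than literally twice one step length;
for symmetric gait the two coincide, and for asymmetric gait the sum
degrades gracefully.

**Domain handling.** A measured $h > 2l$ (outside the pendulum domain) is
possible only under gross artifact; such strides are dropped and counted
rather than propagated as complex numbers.

## Calibration: fitting and choosing zones

Given paired app/reference step lengths, `fit_zone_coefficients` lays a
zone grid of a chosen width (anchored at 0.2 m, the first edge of the
built-in table) over the observed range of app estimates and sets each
zone's coefficient to mean(reference)/mean(estimate) over the pairs whose
estimate falls in the zone. The ratio of means equals 1 under no bias and
is the through-origin least-squares slope under homoscedastic
multiplicative error; fit-then-apply reproduces per-zone reference means
exactly. Zones with fewer than two pairs inherit the nearest populated
zone's coefficient and are flagged.

`select_interval` evaluates candidate widths 0.10–0.50 m in 0.05 m steps:
for each width it fits coefficients, adjusts the estimates, and records
the Passing–Bablok slope and intercept of adjusted-versus-reference. The
selected width minimizes $|\mathrm{slope} - 1|$, with ties broken by
smaller $|\mathrm{intercept}|$ and then by smaller width. The search is a
deterministic function of its inputs.

One behaviour of this search is worth knowing. When several candidate
grids can represent the true bias structure — in particular when narrow
grids nest the breakpoints of the true one — those candidates fit the
calibration data essentially equally well and the lexicographic winner
among them is decided by noise; and when the estimate noise moves pairs
across true breakpoints, the zone-by-estimate convention slightly
contaminates the fit of any grid whose edges coincide with those
breakpoints. The generating width is therefore not reliably the selected
one; what is stable is that the selected width adjusts the bias to a slope
near 1 and an intercept near 0, which is the quantity the selection
criterion actually optimizes.

## Agreement and reliability statistics

**Passing–Bablok orthogonal regression** (`passing_bablok`): the slope is
the shifted median of all pairwise slopes $S_{ij}$, excluding undefined
values ($x_i = x_j$) and slopes exactly $-1$, with offset
$K = \#\{S_{ij} < -1\}$; the intercept is $\mathrm{median}(y - bx)$.
Confidence bounds use the large-sample normal approximation for the slope
ranks (exact small-sample tables are out of scope); even-count medians
average the two central order statistics. The implementation is verified
in the test suite against an independently written brute-force enumeration.

**Bland–Altman** (`bland_altman`): bias is the mean paired difference and
the limits of agreement are bias ± 1.96 sample SDs (multiplier
configurable). Per-pair means are returned for plotting error against
magnitude. Per-stride pairs from one subject are not independent; the
limits are descriptive, and the validate report says so.

**ICC(1,1)** (`icc_1_1`): one-way random-effects, single-measure
intraclass correlation from the ANOVA mean squares,
$(\mathrm{MSB} - \mathrm{MSW}) / (\mathrm{MSB} + (k-1)\mathrm{MSW})$, with
F-based confidence bounds. Reliability bands: excellent above 0.75, good
from 0.6 to 0.75 inclusive, fair from 0.4 up to 0.6, poor below 0.4
(lower-inclusive bands except "excellent", which is strictly above 0.75).

## The synthetic generator

`simulate_imu_walk` produces recordings whose vertical kinematics satisfy
the pendulum model *exactly*, so recovery errors measure the estimator,
not the fixture: within each step the stance angle sweeps
$-\theta_0 \to \theta_0$ with zero angular rate at the contacts
($\theta(\tau) = -\theta_0\cos(\pi\tau/T)$), giving
$z = l(\cos\theta - \cos\theta_0)$, per-step excursion
$h = l(1-\cos\theta_0)$ and commanded step length $2l\sin\theta_0$ — the
pendulum formula applied to the truth values returns the commanded step
length to machine precision. The vertical acceleration is the analytic
second derivative plus gravity, rotated into the device frame by a
constant orientation quaternion, with optional constant accelerometer
bias and seeded Gaussian noise. Defaults describe a healthy adult: 0.60 m
steps, 1.8 steps/s, 0.9 m leg length, 100 Hz, 1 s standing lead-in and
tail.

Heel-strike transients are Hann-windowed 15 Hz bursts (amplitude 3 m/s²,
duration 0.1 s) built as the exact second derivative of a compactly
supported $C^1$ position transient, so they carry zero net impulse and
zero net displacement; an exponentially decaying burst would inject a
spurious velocity kick into every double integration. Three further
choices make the sampled acceleration *discretely* consistent with the
generated position under trapezoid integration (to ~5 × 10⁻⁵ m RMS):
heel-strike times are quantized to the sample grid (the quantized times
and durations are the recorded truth), samples on a step boundary take
the midpoint of the left/right acceleration limits (the onset jump would
otherwise leak a permanent ~0.016 m/s velocity offset), and each sampled
burst is projected onto the null space of the discrete net-velocity and
net-displacement functionals with two smooth correction shapes of
negligible amplitude.

`simulate_paired_steps` emulates calibration data: references drawn
uniformly (default range 0.28–0.81 m, the widest range consistent with
the built-in zone grid and coefficients), estimates constructed as
ref/coefficient with the zone chosen consistently on the estimate
(inconsistent draws are redrawn and counted; ties among consistent zones
are resolved at random), then Gaussian noise (SD 0.02 m) is added to the
estimate. With zero noise, adjusting with the generating coefficients
recovers the references exactly.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: double support and soft-tissue dynamics,
left/right asymmetry (expressible through per-step step lengths and
stride times, but not modeled by default), turning,
pocket slip and phone rattle, time-varying orientation (the gyroscope
stream is zero-mean noise in constant-orientation trials), magnetometer
content, and the real relationship between pocket kinematics and
center-of-mass kinematics — the very bias the zone correction exists for.
Synthetic recovery results validate the signal-processing chain, not the
clinical accuracy of the pendulum model.

## Problem sizes used in tests and the acceptance script

Simulated trials are 30 s (52 steps) for pipeline recovery checks and
10–15 s for orchestration checks; calibration uses 400 pairs; the
reliability demonstration uses 8 synthetic subjects by 3 trials;
statistic oracles run on up to 100 seeded datasets of at most 50 pairs
and 1000 random ICC matrices. These sizes give stable estimates of every
reported quantity while keeping the whole suite comfortably fast.

## Known limitations

- The complementary filter estimates tilt only; prolonged dynamic
  maneuvers between standing phases can bias the gravity reference.
- The zone correction is piecewise-constant, so adjusted step lengths are
  discontinuous at zone boundaries; steps near a boundary inherit that
  quantization (a continuous correction is a natural extension).
- Passing–Bablok confidence bounds use the normal approximation and are
  approximate below ~20 pairs.
- The pipeline assumes straight-line walking; turns are only handled by
  the stride-duration gate.
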