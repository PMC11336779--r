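## Ground-truth-annotated synthetic inputs.
##
## (a) Pocket-IMU walking trials whose vertical kinematics follow the
##     inverted-pendulum model exactly, so the model identities hold on the
##     truth values to machine precision: within each step the stance-leg
##     angle sweeps -theta0 -> theta0 with zero angular rate at the
##     contacts, giving z(t) = l (cos theta - cos theta0), per-step
##     excursion h = l (1 - cos theta0) and commanded step length
##     2 l sin theta0.
## (b) Paired app-vs-reference step-length sets with a configurable
##     piecewise multiplicative bias, emulating the length-dependent bias
##     the zone correction removes.
##
## Heel-strike impact transients are Hann-windowed 15 Hz bursts built as
## the exact second derivative of a compactly supported C1 position
## transient, so they carry zero net impulse and zero net displacement:
## the noiseless acceleration trapezoid-integrates back to the generated
## z(t), which an exponentially decaying burst (nonzero time integral)
## would break.

#' Build a synthetic walk profile
#'
#' Collects the generator parameters for one simulated walking trial.
#' Defaults describe a healthy-adult trial: 0.60 m steps, 1.8 steps/s
#' cadence, 0.9 m leg length, 100 Hz sampling, 1 s standing lead-in and
#' tail (trials start from standing).
#'
#' @param n_steps Number of steps (ignored when `step_lengths` is given).
#' @param step_length Commanded step length in m (scalar; must be <
#'   2 * leg_length).
#' @param cadence Steps per second (sets the step duration; ignored when
#'   `stride_times` is given).
#' @param leg_length Leg length, m.
#' @param fs Sampling frequency, Hz.
#' @param step_lengths Optional per-step lengths, m (overrides `n_steps` /
#'   `step_length`).
#' @param stride_times Optional per-stride durations, s (each stride = two
#'   steps; length `ceiling(n_steps / 2)`); must lie in [0.5, 2.5].
#' @param orientation Constant device orientation as a scalar-first unit
#'   quaternion (device-to-global); identity by default. See
#'   [orientation_from_tilt()].
#' @param noise_sd Additive white accelerometer noise SD per axis, m/s^2.
#' @param gyro_noise_sd Gyroscope noise SD per axis, rad/s.
#' @param accel_bias Constant accelerometer bias, m/s^2 (length 1 or 3,
#'   device frame).
#' @param impact_amp Heel-strike transient amplitude, m/s^2 (default 3).
#' @param impact_freq Transient carrier frequency, Hz (default 15; kept
#'   well above the < 3 Hz gait band so the event prefilter smooths it).
#' @param impact_dur Transient duration, s (default 0.1).
#' @param lead_in_s,tail_s Standing time before / after the walk, s.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param seed Integer seed making all stochastic output reproducible;
#'   `NULL` uses the current RNG stream.
#' @return A `walk_profile` object.
#' @export
walk_profile <- function(n_steps = 52, step_length = 0.6, cadence = 1.8,
                         leg_length = 0.9, fs = 100,
                         step_lengths = NULL, stride_times = NULL,
                         orientation = c(1, 0, 0, 0),
                         noise_sd = 0, gyro_noise_sd = 0,
                         accel_bias = 0,
                         impact_amp = 3, impact_freq = 15, impact_dur = 0.1,
                         lead_in_s = 1, tail_s = 1,
                         gravity = 9.80665, seed = NULL) {
  if (is.null(step_lengths)) {
    if (n_steps < 1) stop_input("profile has no steps")
    step_lengths <- rep(step_length, n_steps)
  }
  n_steps <- length(step_lengths)
  if (n_steps < 1) stop_input("profile has no steps")
  if (leg_length <= 0 || fs <= 0) stop_input("leg_length and fs must be positive")
  if (any(step_lengths <= 0) || any(step_lengths >= 2 * leg_length)) {
    stop_input("step lengths must lie in (0, 2 * leg_length)")
  }
  if (is.null(stride_times)) {
    if (cadence <= 0) stop_input("cadence must be positive")
    stride_times <- rep(2 / cadence, ceiling(n_steps / 2))
  }
  if (length(stride_times) != ceiling(n_steps / 2)) {
    stop_input("need one stride_time per stride (%d), got %d",
               ceiling(n_steps / 2), length(stride_times))
  }
  if (any(stride_times < 0.5) || any(stride_times > 2.5)) {
    stop_input("stride_times must lie in [0.5, 2.5] s")
  }
  if (length(orientation) != 4 || abs(sqrt(sum(orientation^2)) - 1) > 1e-6) {
    stop_input("orientation must be a unit quaternion (scalar first)")
  }
  step_durations <- rep(stride_times / 2, each = 2)[seq_len(n_steps)]
  structure(list(
    step_lengths = step_lengths, stride_times = stride_times,
    step_durations = step_durations,
    leg_length = leg_length, fs = fs,
    orientation = orientation / sqrt(sum(orientation^2)),
    noise_sd = noise_sd, gyro_noise_sd = gyro_noise_sd,
    accel_bias = accel_bias,
    impact_amp = impact_amp, impact_freq = impact_freq,
    impact_dur = impact_dur,
    lead_in_s = lead_in_s, tail_s = tail_s,
    gravity = gravity, seed = seed
  ), class = "walk_profile")
}

#' Constant device tilt as a quaternion
#'
#' Convenience constructor for the `orientation` field of [walk_profile()]:
#' a constant tilt of the device away from vertical.
#'
#' @param tilt_deg Tilt angle in degrees.
#' @param axis Rotation axis in the global frame (default pitch about y).
#' @return A scalar-first unit quaternion.
#' @export
orientation_from_tilt <- function(tilt_deg, axis = c(0, 1, 0)) {
  quat_axis_angle(axis, tilt_deg * pi / 180)
}

## Unit-amplitude impact waveform and its exact second derivative on a
## local time axis tau in [0, d]: position w = sin(a tau) sin^2(b tau)
## with a = 2 pi f, b = pi / d (C1, compact support, zero net impulse).
impact_waveforms <- function(tau, f, d) {
  a <- 2 * pi * f
  b <- pi / d
  w <- sin(a * tau) * sin(b * tau)^2
  wpp <- 0.5 * (-a^2 * sin(a * tau) +
                  0.5 * ((a + 2 * b)^2 * sin((a + 2 * b) * tau) +
                         (a - 2 * b)^2 * sin((a - 2 * b) * tau)))
  list(w = w, wpp = wpp)
}

#' Simulate a pocket-IMU walking trial
#'
#' Generates the vertical centre-of-mass trajectory of an inverted-pendulum
#' walk plus heel-strike transients, differentiates it analytically, adds
#' gravity, rotates the result into the device frame by the profile's
#' constant orientation, and corrupts it with seeded Gaussian noise and a
#' constant accelerometer bias. Ground truth (event times, per-step h and
#' step lengths, the generated z series) accompanies the recording.
#'
#' @param profile A [walk_profile()].
#' @return List with elements `recording` (an [imu_recording()]) and
#'   `truth` (a `synthetic_truth`: `events_t` heel-strike times in s,
#'   `steps` data frame with `step_index, t_hs_s, duration_s, h_true_m,
#'   step_length_true_m`, `z_true` and `t` the noiseless vertical position
#'   series, and the echoed `profile`).
#' @export
simulate_imu_walk <- function(profile) {
  if (!inherits(profile, "walk_profile")) stop_input("profile must be a walk_profile")
  with_seed(profile$seed, {
    l <- profile$leg_length
    fs <- profile$fs
    dt <- 1 / fs
    sl <- profile$step_lengths
    n_steps <- length(sl)
    ## Heel-strike times are quantized to the sample grid: the quantized
    ## times and the step durations derived from them ARE the recorded
    ## truth, so event bookkeeping is exact at the native resolution and
    ## sampled accelerations carry no partial-sample boundary panels.
    t_hs <- round((profile$lead_in_s +
                     c(0, cumsum(profile$step_durations))) * fs) / fs
    durT <- diff(t_hs)
    total <- t_hs[n_steps + 1] + profile$tail_s
    n <- floor(total * fs) + 1
    t <- (seq_len(n) - 1) * dt

    z <- numeric(n)
    zpp <- numeric(n)
    theta0 <- asin(sl / (2 * l))
    trap_end <- function(x) {  # final value of cumtrapz at unit spacing
      sum(x) - (x[1] + x[length(x)]) / 2
    }
    ctz <- function(x) cumsum(x) - (x + x[1]) / 2
    pad <- function(x) c(0, x, 0)
    ## Project a compactly supported sampled acceleration onto the null
    ## space of the discrete net-velocity and net-displacement trapezoid
    ## functionals, using two smooth correction shapes over the support.
    ## The continuous contribution of every step (and burst) integrates to
    ## zero velocity and displacement; this enforces the same for the
    ## sampled series, so cumulative-trapezoid double integration carries
    ## no O(dt^2) drift across segment boundaries.
    project_zero_sum <- function(b, tau, dur) {
      u <- cos(pi * (tau - dur / 2) / dur)^2
      r <- u * (tau - dur / 2) / dur
      M <- matrix(c(trap_end(pad(u)), trap_end(pad(r)),
                    trap_end(ctz(pad(u))), trap_end(ctz(pad(r)))),
                  2, 2, byrow = TRUE)
      ab <- solve(M, c(trap_end(pad(b)), trap_end(ctz(pad(b)))))
      b - ab[1] * u - ab[2] * r
    }
    for (k in seq_len(n_steps)) {
      idx <- which(t >= t_hs[k] & t < t_hs[k + 1])
      if (length(idx) == 0) next
      tau <- t[idx] - t_hs[k]
      b <- pi / durT[k]
      th <- -theta0[k] * cos(b * tau)
      thp <- theta0[k] * b * sin(b * tau)
      thpp <- theta0[k] * b^2 * cos(b * tau)
      z[idx] <- l * (cos(th) - cos(theta0[k]))
      zpp[idx] <- -l * (thpp * sin(th) + thp^2 * cos(th))
    }
    ## The acceleration is discontinuous at step boundaries (zero during
    ## standing, kinks between unequal steps). Samples falling exactly on
    ## a boundary take the midpoint of the left and right limits, which
    ## restores second-order trapezoid accuracy across the jump (otherwise
    ## the onset jump alone leaks a permanent ~0.016 m/s velocity offset
    ## into any double integration).
    Lb <- l * theta0 * (pi / durT)^2 * sin(theta0)
    bidx <- as.integer(round(t_hs * fs)) + 1L
    ok_b <- bidx >= 1 & bidx <= n
    zpp[bidx[ok_b]] <- ((c(0, Lb) + c(Lb, 0)) / 2)[ok_b]

    ## Heel-strike transients. The analytic burst has zero net impulse and
    ## displacement, but its DISCRETE trapezoid sums do not vanish at gait
    ## sampling rates (15 Hz carrier at 100 Hz), which would leak a small
    ## velocity kick into every double-integration. Each sampled burst is
    ## therefore projected onto the null space of the two trapezoid
    ## functionals (net velocity, net displacement) using two smooth
    ## compact correction shapes; the truth z then carries the burst's
    ## exact discrete double integral, making acceleration and position
    ## consistent under trapezoid integration to machine precision.
    if (profile$impact_amp > 0) {
      d <- profile$impact_dur
      tau_fine <- seq(0, d, length.out = 2001)
      unit_max <- max(abs(impact_waveforms(tau_fine, profile$impact_freq, d)$wpp))
      A <- profile$impact_amp / unit_max
      for (te in t_hs) {
        idx <- which(t >= te & t < te + d)
        if (length(idx) < 5) next
        tau <- t[idx] - te
        b <- A * impact_waveforms(tau, profile$impact_freq, d)$wpp
        b <- project_zero_sum(b, tau, d)
        v_loc <- ctz(pad(b)) * dt
        z_loc <- ctz(v_loc) * dt
        zpp[idx] <- zpp[idx] + b
        z[idx] <- z[idx] + z_loc[2:(length(idx) + 1)]
      }
    }

    ## device-frame channels: a_dev = R^T (0, 0, zpp + g)
    R <- quat_to_matrix(profile$orientation)
    az_plus_g <- zpp + profile$gravity
    acc <- cbind(az_plus_g * R[3, 1], az_plus_g * R[3, 2], az_plus_g * R[3, 3])
    bias <- rep(profile$accel_bias, length.out = 3)
    acc <- sweep(acc, 2, bias, "+")
    if (profile$noise_sd > 0) {
      acc <- acc + matrix(rnorm(3 * n, 0, profile$noise_sd), n, 3)
    }
    gyr <- if (profile$gyro_noise_sd > 0) {
      matrix(rnorm(3 * n, 0, profile$gyro_noise_sd), n, 3)
    } else {
      matrix(0, n, 3)
    }

    rec <- imu_recording(
      data.frame(t = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                 gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3]),
      fs = fs, subject_id = "synthetic", leg_length = l,
      condition = "unknown"
    )
    truth <- structure(list(
      events_t = t_hs,
      steps = data.frame(
        step_index = seq_len(n_steps),
        t_hs_s = t_hs[seq_len(n_steps)],
        duration_s = durT,
        h_true_m = l * (1 - cos(theta0)),
        step_length_true_m = sl
      ),
      z_true = z, t = t,
      profile = profile
    ), class = "synthetic_truth")
    list(recording = rec, truth = truth)
  })
}

#' Simulate paired app-vs-reference step lengths with piecewise bias
#'
#' Draws reference step lengths uniformly on `ref_range` and constructs the
#' app estimate as est = ref / coefficient(zone), where the zone is the one
#' the ESTIMATE falls in (matching how the correction is later applied):
#' for each draw, every zone j with ref / coeff_j inside zone j is
#' consistent; one is picked at random among them, and draws with no
#' consistent zone are redrawn (counted). Gaussian noise is then added to
#' the estimate. Applying the same coefficients to the noiseless estimates
#' recovers the references exactly.
#'
#' @param n Number of pairs (>= 2).
#' @param ref_range Range of reference step lengths, m. The default
#'   (0.28, 0.81) is the widest range consistent with the default zone
#'   grid and coefficients.
#' @param zone_edges Zone breakpoints, m.
#' @param zone_coeffs True multiplicative coefficients, one per zone.
#' @param noise_sd SD of additive noise on the estimate, m.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with `paired` (a [paired_steps()]), `truth` (data frame
#'   `zone, est_noiseless`), and `n_redrawn`.
#' @export
simulate_paired_steps <- function(n, ref_range = c(0.28, 0.81),
                                  zone_edges = c(0.2, 0.5, 0.8, 1.1),
                                  zone_coeffs = c(1.37, 1.02, 0.74),
                                  noise_sd = 0.02, seed = NULL) {
  if (n < 2) stop_input("need n >= 2 pairs")
  if (length(zone_coeffs) != length(zone_edges) - 1 || any(zone_coeffs <= 0)) {
    stop_input("need one positive coefficient per zone")
  }
  with_seed(seed, {
    nz <- length(zone_coeffs)
    est <- ref <- est0 <- numeric(n)
    zone <- integer(n)
    filled <- 0L
    redraws <- 0L
    attempts <- 0L
    max_attempts <- 1000L * n
    while (filled < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_compute("impossible configuration: no consistent zone for ref_range after %d attempts",
                     max_attempts)
      }
      r <- runif(1, ref_range[1], ref_range[2])
      e_cand <- r / zone_coeffs
      z_cand <- findInterval(e_cand, zone_edges, rightmost.closed = TRUE)
      consistent <- which(z_cand == seq_len(nz))
      if (length(consistent) == 0) {
        redraws <- redraws + 1L
        next
      }
      j <- if (length(consistent) == 1) consistent else
        consistent[sample.int(length(consistent), 1)]
      e <- e_cand[j] + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
      if (e <= 0) {
        redraws <- redraws + 1L
        next
      }
      filled <- filled + 1L
      ref[filled] <- r
      est[filled] <- e
      est0[filled] <- e_cand[j]
      zone[filled] <- j
    }
    if (redraws > 0) {
      message(sprintf("simulate_paired_steps: redrew %d draw(s) without a consistent zone",
                      redraws))
    }
    list(paired = paired_steps(est, ref),
         truth = data.frame(zone = zone, est_noiseless = est0),
         n_redrawn = redraws)
  })
}
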