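## Heel-strike detection and stride segmentation.
##
## The vertical acceleration of a pocket-carried phone peaks at each heel
## strike (the body vaults onto the new stance leg) with impact ringing on
## top. A 3 Hz zero-phase low-pass keeps the gait fundamental and first
## harmonic while collapsing the ringing into the single underlying peak;
## peaks are then selected by topographic prominence relative to the robust
## dispersion of the filtered signal, which makes detection invariant to
## amplitude scaling (subject mass, phone placement).

## Topographic prominence of local maxima at indices `peaks` of series x:
## height above the higher of the two deepest valleys separating the peak
## from higher terrain (or the series boundary).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p
    left_min <- h
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      if (x[i] < left_min) left_min <- x[i]
    }
    i <- p
    right_min <- h
    n <- length(x)
    while (i < n) {
      i <- i + 1
      if (x[i] > h) break
      if (x[i] < right_min) right_min <- x[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect heel strikes from vertical acceleration
#'
#' Low-pass filters the vertical acceleration (zero-phase, 4th order) and
#' picks local maxima whose prominence exceeds
#' `prominence_k * mad(filtered)` while enforcing a refractory period of
#' `min_period` seconds between events (peaks are accepted in decreasing
#' order of prominence).
#'
#' @param az A `global_vertical` series.
#' @param lp_cutoff Low-pass prefilter cutoff in Hz (default 3).
#' @param min_period Minimum time between consecutive heel strikes, s
#'   (default 0.4, i.e. a 2.5 steps/s cadence ceiling).
#' @param prominence_k Prominence threshold as a multiple of the robust SD
#'   (1.4826 * MAD) of the filtered series.
#' @return A `gait_events` object: list with `hs_idx` (ascending sample
#'   indices), `to_idx` (empty; toe-off labelling is not performed) and
#'   `fs`. An empty event set is returned when nothing crosses threshold.
#' @export
detect_heel_strikes <- function(az, lp_cutoff = 3, min_period = 0.4,
                                prominence_k = 1.0) {
  if (!inherits(az, "global_vertical")) stop_input("az must be a global_vertical")
  x <- butter_zero_phase(az$az_global, az$fs, lp_cutoff, 4, "lowpass")

  ## strict local maxima
  dx <- diff(x)
  cand <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  events <- integer(0)
  if (length(cand) > 0) {
    prom <- peak_prominence(x, cand)
    ## robust dispersion, floored at a fraction of the SD: the MAD
    ## collapses on sparse impulse-like series (mostly-flat baseline),
    ## where filter ripple would otherwise pass any MAD-relative
    ## threshold; the floor keeps the threshold scale-invariant and is
    ## inert on dense oscillatory walking signals (where MAD ~ SD)
    robust_sd <- max(mad(x), 0.25 * sd(x))
    thr <- prominence_k * robust_sd
    sel <- prom >= thr & prom > 0
    keep <- cand[sel]
    prom <- prom[sel]
    if (length(keep) > 0) {
      ## greedy refractory enforcement, most prominent first
      ord <- order(prom, decreasing = TRUE)
      min_gap <- min_period * az$fs
      accepted <- integer(0)
      for (i in ord) {
        if (all(abs(keep[i] - accepted) >= min_gap)) {
          accepted <- c(accepted, keep[i])
        }
      }
      events <- sort(accepted)
    }
  }
  structure(list(hs_idx = events, to_idx = integer(0), fs = az$fs),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events: %d heel strikes at %g Hz\n", length(x$hs_idx), x$fs))
  invisible(x)
}

#' Segment heel strikes into strides
#'
#' A stride spans two consecutive heel strikes of the same foot. With a
#' single pocket IMU, foot identity is assigned by alternation: stride k
#' runs from heel strike k to heel strike k+2, bracketing one contralateral
#' strike. Strides whose duration falls outside the physiologic gate are
#' excluded and counted (turn artifacts, missed events).
#'
#' @param events A `gait_events` object with at least 3 heel strikes.
#' @param gate Admissible stride-duration interval in seconds
#'   (default `c(0.5, 2.5)`).
#' @return A `stride_segmentation` data frame with columns `hs_i`,
#'   `hs_mid`, `hs_next` (sample indices) and `stride_time` (s); attribute
#'   `n_excluded` counts the duration-gated strides.
#' @export
segment_strides <- function(events, gate = c(0.5, 2.5)) {
  if (!inherits(events, "gait_events")) stop_input("events must be a gait_events")
  hs <- events$hs_idx
  if (length(hs) < 3) {
    stop_compute("insufficient events: need at least 3 heel strikes, got %d",
                 length(hs))
  }
  k <- seq_len(length(hs) - 2)
  seg <- data.frame(
    hs_i = hs[k],
    hs_mid = hs[k + 1],
    hs_next = hs[k + 2],
    stride_time = (hs[k + 2] - hs[k]) / events$fs
  )
  ok <- seg$stride_time >= gate[1] & seg$stride_time <= gate[2]
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(sprintf("segment_strides: excluded %d stride(s) outside [%g, %g] s",
                    n_excluded, gate[1], gate[2]))
  }
  seg <- seg[ok, , drop = FALSE]
  rownames(seg) <- NULL
  attr(seg, "n_excluded") <- n_excluded
  class(seg) <- c("stride_segmentation", "data.frame")
  seg
}
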