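## The inverted-pendulum core: vertical displacement by double integration,
## per-step height change h, step length 2*sqrt(2*h*l - h^2), stride speed.

#' Vertical position by drift-free double integration
#'
#' Doubly integrates the vertical acceleration (cumulative trapezoid at the
#' native sampling grid) and removes integration drift with a 4th-order
#' zero-lag Butterworth high-pass at 0.11 Hz applied to the position
#' series. Two numerical-stability guards precede the mandated high-pass:
#' the acceleration mean over the trial is removed before integration
#' (bounding the parabolic drift), and the least-squares linear trend of
#' the raw position (the ramp produced by the unobservable initial
#' velocity, which lies in the high-pass's DC null space) is subtracted
#' before filtering so its edge transients never enter the filter.
#' Velocity is not filtered.
#'
#' @param az A `global_vertical` series.
#' @param hp_cutoff High-pass cutoff in Hz (default 0.11).
#' @param hp_order Filter order (default 4).
#' @return A `vertical_position`: list with `z_pos` (m, zero-mean) and `fs`.
#' @export
vertical_position <- function(az, hp_cutoff = 0.11, hp_order = 4) {
  if (!inherits(az, "global_vertical")) stop_input("az must be a global_vertical")
  a <- az$az_global - mean(az$az_global)
  dt <- 1 / az$fs
  tgrid <- (seq_along(a) - 1) * dt
  v <- as.numeric(pracma::cumtrapz(tgrid, a))
  z <- as.numeric(pracma::cumtrapz(tgrid, v))
  ## remove the least-squares linear trend before filtering: the ramp from
  ## the unobservable initial-velocity constant lies in the filter's DC
  ## null space anyway, but subtracting it exactly avoids dragging its
  ## (large) edge transients through the finite-length filter
  co <- stats::lm.fit(cbind(1, tgrid), z)$coefficients
  z <- z - co[1] - co[2] * tgrid
  z <- butter_zero_phase(z, az$fs, hp_cutoff, hp_order, "highpass")
  structure(list(z_pos = z, fs = az$fs), class = "vertical_position")
}

#' Vertical excursion over one step
#'
#' Peak-to-trough change in vertical position within a step window (heel
#' strike to the next, contralateral, heel strike). This matches the
#' pendulum geometry: the body apex falls mid-window, the contacts at its
#' edges.
#'
#' @param z_pos A `vertical_position` series.
#' @param window Integer vector `c(from, to)` of sample indices (inclusive).
#' @return Height change h in meters (>= 0).
#' @export
step_height <- function(z_pos, window) {
  if (!inherits(z_pos, "vertical_position")) stop_input("z_pos must be a vertical_position")
  if (length(window) != 2) stop_input("window must be c(from, to)")
  from <- window[1]; to <- window[2]
  n <- length(z_pos$z_pos)
  if (from > to || from < 1 || to > n) stop_input("empty or out-of-range window")
  seg <- z_pos$z_pos[from:to]
  max(seg) - min(seg)
}

#' Inverted-pendulum step length
#'
#' Step length from leg length l and per-step vertical excursion h, under
#' the model that the body vaults over a rigid stance leg:
#' \deqn{\mathrm{step\ length} = 2\sqrt{2hl - h^2}.}
#' Strictly increasing in h on \eqn{[0, l]}, with the identities
#' h = 0 giving 0 and h = l giving 2l.
#'
#' @param h Vertical excursion per step, m. Must satisfy 0 <= h <= 2l.
#' @param l Leg length, m (> 0). Recycled against `h`.
#' @return Step length in meters (vectorized).
#' @examples
#' step_length_pendulum(0.05, 0.9)   # ~0.5916 m
#' @export
step_length_pendulum <- function(h, l) {
  if (any(!is.finite(h)) || any(!is.finite(l))) stop_input("h and l must be finite")
  if (any(l <= 0)) stop_input("leg length must be positive")
  if (any(h < 0)) stop_input("h must be non-negative")
  if (any(h > 2 * l)) {
    stop_input("h = %g exceeds 2*l = %g: pendulum radicand negative",
               max(h), 2 * max(l))
  }
  2 * sqrt(2 * h * l - h^2)
}

#' Full single-IMU gait estimation pipeline
#'
#' Orchestrates orientation estimation, rotation to the global frame, heel
#' strike detection, stride segmentation, double integration and the
#' pendulum model into a per-stride table of raw (unadjusted) gait
#' parameters. Stride length is the sum of the two step lengths within the
#' stride (equal to twice the step length for symmetric gait); speed is
#' stride length over stride time.
#'
#' @param rec An [imu_recording()] with `leg_length` set.
#' @param config Pipeline parameters, see [default_config()].
#' @param coeffs Optional [coefficient_table()]; when supplied the adjusted
#'   columns are filled via [adjust_stride_table()].
#' @return A `stride_table` data frame (one row per retained stride) with
#'   columns `stride_index, t_start_s, stride_time_s, h1_m, h2_m,
#'   step_length_1_m, step_length_2_m, step_length_adj_1_m,
#'   step_length_adj_2_m, zone_1, zone_2, stride_length_m, speed_mps,
#'   speed_adj_mps` (adjusted columns `NA` unless `coeffs` is given).
#'   Attribute `n_excluded` counts strides dropped by the duration gate or
#'   a pendulum domain violation (h > 2l).
#' @export
estimate_gait <- function(rec, config = default_config(), coeffs = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  if (is.na(rec$leg_length)) stop_input("recording has no leg_length; the pendulum model needs it")
  cfg <- merge_config(default_config(), config)

  q <- estimate_orientation(rec, method = cfg$orientation$method,
                            gain = cfg$orientation$gain)
  gv <- rotate_to_global(rec, q, g = cfg$gravity_mps2)
  ev <- detect_heel_strikes(gv,
                            lp_cutoff = cfg$events$lp_cutoff_hz,
                            min_period = cfg$events$min_period_s,
                            prominence_k = cfg$events$prominence_k)
  if (length(ev$hs_idx) < 3) {
    stop_compute("insufficient events: %d heel strike(s) detected, need >= 3",
                 length(ev$hs_idx))
  }
  seg <- segment_strides(ev, gate = cfg$events$stride_gate_s)
  zp <- vertical_position(gv, hp_cutoff = cfg$pendulum$hp_cutoff_hz,
                          hp_order = cfg$pendulum$hp_order)

  l <- rec$leg_length
  n_excluded <- attr(seg, "n_excluded")
  rows <- lapply(seq_len(nrow(seg)), function(k) {
    h1 <- step_height(zp, c(seg$hs_i[k], seg$hs_mid[k]))
    h2 <- step_height(zp, c(seg$hs_mid[k], seg$hs_next[k]))
    if (h1 > 2 * l || h2 > 2 * l) return(NULL)  # outside pendulum domain
    sl1 <- step_length_pendulum(h1, l)
    sl2 <- step_length_pendulum(h2, l)
    stride_length <- sl1 + sl2
    data.frame(
      t_start_s = rec$data$t[seg$hs_i[k]],
      stride_time_s = seg$stride_time[k],
      h1_m = h1, h2_m = h2,
      step_length_1_m = sl1, step_length_2_m = sl2,
      stride_length_m = stride_length,
      speed_mps = stride_length / seg$stride_time[k]
    )
  })
  dropped_domain <- sum(vapply(rows, is.null, logical(1)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop_compute("no strides survived gating")
  tab <- do.call(rbind, rows)
  tab <- cbind(stride_index = seq_len(nrow(tab)), tab)
  tab$step_length_adj_1_m <- NA_real_
  tab$step_length_adj_2_m <- NA_real_
  tab$zone_1 <- NA_integer_
  tab$zone_2 <- NA_integer_
  tab$speed_adj_mps <- NA_real_
  tab <- tab[, STRIDE_TABLE_COLS]
  attr(tab, "n_excluded") <- n_excluded + dropped_domain
  attr(tab, "leg_length") <- l
  class(tab) <- c("stride_table", "data.frame")
  if (!is.null(coeffs)) tab <- adjust_stride_table(tab, coeffs)
  tab
}
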