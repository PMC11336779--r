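## Device orientation and the gravity-aligned vertical channel.
##
## Only the vertical axis matters for the pendulum model, so orientation is
## estimated as a tilt filter: gyroscope integration continuously corrected
## toward the low-passed accelerometer gravity direction (a complementary
## filter). Heading/yaw is unobservable from gravity and irrelevant here;
## the magnetometer is ignored.

#' Estimate device orientation over a recording
#'
#' Produces one unit quaternion (scalar-first) per sample encoding the
#' rotation from the device frame to a gravity-aligned global frame
#' (z-axis up). Orientation is initialized from the mean accelerometer
#' vector over the first 0.5 s, assumed quasi-static (trials start from
#' standing), then propagated with the gyroscope; the default
#' `tilt_complementary` method additionally nudges the estimated "up"
#' direction toward the low-passed accelerometer direction each sample.
#'
#' @param rec An [imu_recording()].
#' @param method `"tilt_complementary"` (default) or `"gyro_only"`
#'   (dead-reckoning from the initial pose, no accelerometer correction).
#' @param gain Complementary-filter correction gain per sample
#'   (unitless, default 0.02 at 100 Hz).
#' @return An `orientation_series`: list with `q` (n x 4 matrix of unit
#'   quaternions) and `fs`.
#' @export
estimate_orientation <- function(rec,
                                 method = c("tilt_complementary", "gyro_only"),
                                 gain = 0.02) {
  stopifnot(inherits(rec, "imu_recording"))
  method <- match.arg(method)
  d <- rec$data
  n <- nrow(d)
  dt <- 1 / rec$fs
  acc <- cbind(d$ax, d$ay, d$az)
  gyr <- cbind(d$gx, d$gy, d$gz)

  n0 <- max(2L, min(n, as.integer(round(0.5 * rec$fs))))
  a0 <- colMeans(acc[seq_len(n0), , drop = FALSE])
  if (sqrt(sum(a0^2)) < 1e-6) {
    stop_compute("cannot initialize orientation: accelerometer reads zero")
  }
  q <- quat_between(a0 / sqrt(sum(a0^2)), c(0, 0, 1))

  ## first-order low-pass on the accelerometer vector used as the gravity
  ## reference (time constant 0.5 s; suppresses step-frequency content)
  alpha <- dt / (0.5 + dt)
  a_lp <- acc[1, ]

  Q <- matrix(0, n, 4)
  Q[1, ] <- quat_normalize(q)
  if (n > 1) {
    for (k in 2:n) {
      w <- gyr[k - 1, ]
      wn <- sqrt(sum(w^2))
      if (wn > 0) q <- quat_mul(q, quat_axis_angle(w / wn, wn * dt))
      if (method == "tilt_complementary") {
        a_lp <- a_lp + alpha * (acc[k, ] - a_lp)
        an <- sqrt(sum(a_lp^2))
        if (an > 1e-6) {
          u_meas <- a_lp / an
          u_pred <- quat_rotate_inv(q, c(0, 0, 1))
          corr <- vec3_cross(u_meas, u_pred)
          q <- quat_mul(q, c(1, 0.5 * gain * corr))
        }
      }
      q <- quat_normalize(q)
      Q[k, ] <- q
    }
  }
  structure(list(q = Q, fs = rec$fs), class = "orientation_series")
}

#' Rotate a recording into the global frame and extract vertical acceleration
#'
#' Applies the per-sample rotation to the accelerometer vector and removes
#' gravity from the vertical (global z) component.
#'
#' @param rec An [imu_recording()].
#' @param q An `orientation_series` from [estimate_orientation()], same
#'   length as the recording.
#' @param g Gravitational acceleration subtracted from the vertical
#'   component, m/s^2.
#' @return A `global_vertical`: list with `az_global` (m/s^2, positive up,
#'   gravity removed) and `fs`.
#' @export
rotate_to_global <- function(rec, q, g = 9.80665) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!inherits(q, "orientation_series")) stop_input("q must be an orientation_series")
  d <- rec$data
  if (nrow(q$q) != nrow(d)) {
    stop_input("orientation series length (%d) does not match recording length (%d)",
               nrow(q$q), nrow(d))
  }
  Q <- q$q
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  ## third row of R(q), i.e. the global-z component of the rotated vector
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  az_global <- r31 * d$ax + r32 * d$ay + r33 * d$az - g
  global_vertical(az_global, rec$fs)
}

#' Construct a vertical-acceleration series
#'
#' Container for the gravity-removed vertical acceleration. On walking
#' signals the full-trial mean should be near zero; a mean beyond
#' 0.5 m/s^2 indicates residual gravity (bad orientation) and triggers a
#' warning.
#'
#' @param az_global Vertical acceleration, m/s^2, positive up, gravity
#'   removed.
#' @param fs Sampling frequency, Hz.
#' @return A `global_vertical` object.
#' @export
global_vertical <- function(az_global, fs) {
  if (!is.numeric(az_global) || fs <= 0) stop_input("invalid vertical series")
  m <- mean(az_global)
  if (is.finite(m) && abs(m) >= 0.5) {
    warning(sprintf(
      "mean vertical acceleration %.2f m/s^2 exceeds 0.5; residual gravity or bad orientation?",
      m))
  }
  structure(list(az_global = az_global, fs = fs), class = "global_vertical")
}
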