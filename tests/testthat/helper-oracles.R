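# Independent oracles and fixture builders shared across test files.

# Brute-force Passing-Bablok oracle: explicit double loop over all pairs,
# manual K-offset median and rank-based confidence bounds. Written
# independently of the package implementation (loops, no outer/vectorized
# slope matrix) so the two routes only share the method's definition.
pb_oracle <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) slopes <- c(slopes, s)
      }
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- 0
  for (s in slopes) if (s < -1) K <- K + 1
  if (N %% 2 == 1) {
    b <- slopes[(N + 1) / 2 + K]
  } else {
    b <- (slopes[N / 2 + K] + slopes[N / 2 + 1 + K]) / 2
  }
  a <- median(y - b * x)
  w <- qnorm((1 + conf_level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1
  lo <- slopes[min(max(M1 + K, 1), N)]
  hi <- slopes[min(max(M2 + K, 1), N)]
  list(slope = b, intercept = a,
       slope_ci = c(lo, hi),
       intercept_ci = c(median(y - hi * x), median(y - lo * x)))
}

# Closed-form ICC(1,1) oracle via stats::aov (independent ANOVA route).
icc_oracle_aov <- function(m) {
  df <- data.frame(y = as.vector(t(m)),
                   subj = factor(rep(seq_len(nrow(m)), each = ncol(m))))
  av <- summary(stats::aov(y ~ subj, data = df))[[1]]
  msb <- av["subj", "Mean Sq"]
  msw <- av["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Static (standing) recording: constant specific force, zero rates.
make_static_recording <- function(accel = c(0, 0, 9.80665), duration = 5,
                                  fs = 100, leg_length = 0.9) {
  n <- duration * fs + 1
  imu_recording(
    data.frame(t = (seq_len(n) - 1) / fs,
               ax = rep(accel[1], n), ay = rep(accel[2], n),
               az = rep(accel[3], n),
               gx = 0, gy = 0, gz = 0),
    fs = fs, subject_id = "static", leg_length = leg_length
  )
}

# Match each detected stride (row of a stride table) against constant-
# profile truth; returns per-stride absolute errors.
stride_errors <- function(tab, step_length_true, stride_time_true) {
  speed_true <- 2 * step_length_true / stride_time_true
  list(
    stride_time = abs(tab$stride_time_s - stride_time_true),
    step_length = abs(cbind(tab$step_length_1_m, tab$step_length_2_m) -
                        step_length_true),
    speed = abs(tab$speed_mps - speed_true)
  )
}

# Synthetic vertical-acceleration series from explicit values.
gv_series <- function(x, fs = 100) {
  suppressWarnings(global_vertical(x, fs))
}
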