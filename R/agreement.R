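## Method-comparison and reliability statistics: Passing-Bablok orthogonal
## regression, Bland-Altman limits of agreement, and the one-way
## random-effects single-measure intraclass correlation ICC(1,1).

#' Passing-Bablok orthogonal regression
#'
#' Non-parametric regression for method comparison, robust to measurement
#' error in both variables. The slope is the shifted median of all
#' pairwise slopes S_ij = (y_j - y_i) / (x_j - x_i), excluding undefined
#' slopes (x_i = x_j) and slopes exactly equal to -1, with offset
#' K = #\{S_ij < -1\}; the intercept is median(y - slope * x). Confidence
#' bounds use the large-sample normal approximation for the slope ranks,
#' with the intercept bounds derived from the slope bounds.
#'
#' @param x Reference-method values.
#' @param y Test-method values, same length (n >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return A `pb_result`: list with `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `n`.
#' @export
passing_bablok <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_input("need at least 3 pairs, got %d", n)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_input("inputs must be finite")
  if (diff(range(x)) == 0) stop_compute("degenerate input: all x identical")

  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  up <- upper.tri(dx)
  dxx <- dx[up]
  dyy <- dy[up]
  ok <- dxx != 0
  S <- dyy[ok] / dxx[ok]
  S <- S[S != -1]
  N <- length(S)
  if (N == 0) stop_compute("no valid pairwise slopes")
  S <- sort(S)
  K <- sum(S < -1)
  slope <- if (N %% 2 == 1) {
    S[(N + 1) %/% 2 + K]
  } else {
    mean(S[c(N %/% 2 + K, N %/% 2 + 1 + K)])
  }
  intercept <- median(y - slope * x)

  w <- qnorm((1 + conf_level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1
  clamp <- function(i) min(max(i, 1), N)
  slope_ci <- c(S[clamp(M1 + K)], S[clamp(M2 + K)])
  intercept_ci <- c(median(y - slope_ci[2] * x), median(y - slope_ci[1] * x))

  structure(list(slope = slope, intercept = intercept,
                 slope_ci = slope_ci, intercept_ci = intercept_ci,
                 n = n, conf_level = conf_level),
            class = "pb_result")
}

#' @export
print.pb_result <- function(x, ...) {
  cat(sprintf("Passing-Bablok regression (n = %d)\n", x$n))
  cat(sprintf("  slope:     %.4f  [%0.f%% CI %.4f, %.4f]\n",
              x$slope, 100 * x$conf_level, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept: %.4f  [%0.f%% CI %.4f, %.4f]\n",
              x$intercept, 100 * x$conf_level, x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias and limits of agreement of paired differences d = y - x:
#' bias = mean(d), limits = bias +/- multiplier * SD(d) (sample SD). The
#' per-pair means (x + y)/2 are returned for plotting error against the
#' magnitude of the measured quantity.
#'
#' @param x Reference-method values.
#' @param y Test-method values, same length (n >= 2).
#' @param multiplier Half-width of the limits in SD units (default 1.96).
#' @return A `ba_result`: list with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `multiplier`, `n`, `means`, `diffs`.
#' @export
bland_altman <- function(x, y, multiplier = 1.96) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop_input("need at least 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_input("inputs must be finite")
  d <- y - x
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - multiplier * sd_diff,
                 loa_high = bias + multiplier * sd_diff,
                 multiplier = multiplier, n = n,
                 means = (x + y) / 2, diffs = d),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4f, SD %.4f, LoA [%.4f, %.4f] (%.2f SD)\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high, x$multiplier))
  invisible(x)
}

#' Intraclass correlation ICC(1,1)
#'
#' One-way random-effects, single-measure intraclass correlation from the
#' ANOVA mean squares: icc = (MSB - MSW) / (MSB + (k - 1) MSW), where MSB
#' and MSW are the between- and within-subject mean squares of an
#' n-subjects x k-measures matrix. Confidence bounds use the F-distribution
#' (Shrout & Fleiss construction). Rows with missing measures are dropped
#' and counted.
#'
#' @param data Numeric matrix or data frame, subjects in rows, repeated
#'   measures in columns (n >= 2 complete rows, k >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return An `icc_result`: list with `icc`, `model` (`"ICC(1,1)"`),
#'   `n_subjects`, `k_measures`, `ci`, `p_value`, `label`
#'   (see [classify_reliability()]), `n_dropped`.
#' @export
icc_1_1 <- function(data, conf_level = 0.95) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop_input("data must be numeric")
  k <- ncol(m)
  if (k < 2) stop_input("need at least 2 repeated measures (columns)")
  complete <- rowSums(!is.finite(m)) == 0
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop_input("need at least 2 complete subjects, got %d", n)

  grand <- mean(m)
  rm_ <- rowMeans(m)
  msb <- k * sum((rm_ - grand)^2) / (n - 1)
  msw <- sum((m - rm_)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    stop_compute("all values identical; ICC undefined (no variance)")
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)

  if (msw > 0) {
    fobs <- msb / msw
    fl <- fobs / qf((1 + conf_level) / 2, n - 1, n * (k - 1))
    fu <- fobs * qf((1 + conf_level) / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- pf(fobs, n - 1, n * (k - 1), lower.tail = FALSE)
  } else {
    ci <- c(1, 1)
    p <- 0
  }

  structure(list(icc = icc, model = "ICC(1,1)",
                 n_subjects = n, k_measures = k,
                 ci = ci, p_value = p,
                 label = classify_reliability(icc),
                 n_dropped = n_dropped, conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (%s), %d subjects x %d measures, %0.f%% CI [%.3f, %.3f], p = %.3g\n",
              x$model, x$icc, x$label, x$n_subjects, x$k_measures,
              100 * x$conf_level, x$ci[1], x$ci[2], x$p_value))
  if (x$n_dropped > 0) cat(sprintf("  dropped %d incomplete row(s)\n", x$n_dropped))
  invisible(x)
}

#' Classify an ICC value into a reliability band
#'
#' Bands: excellent (> 0.75), good (0.6 to 0.75), fair (0.4 to below 0.6),
#' poor (< 0.4). Bands are lower-inclusive except "excellent", which is
#' strictly above 0.75; so 0.75 and 0.6 are "good" and 0.4 is "fair".
#'
#' @param icc A finite ICC value.
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"poor"`.
#' @export
classify_reliability <- function(icc) {
  if (length(icc) != 1 || !is.finite(icc)) stop_input("icc must be a single finite value")
  if (icc > 0.75) "excellent"
  else if (icc >= 0.6) "good"
  else if (icc >= 0.4) "fair"
  else "poor"
}
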