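## Zone-coefficient step-length correction and its calibration.
##
## The raw pendulum estimate carries a length-dependent multiplicative
## bias: short steps are underestimated, long steps overestimated. The
## correction multiplies each raw step length by a constant chosen by the
## step-length zone the RAW estimate falls in. Zones are half-open
## [low, high) with the last zone closed at the top; out-of-range values
## use the nearest zone's coefficient and are flagged.

#' Construct a zone-coefficient table
#'
#' @param zone_edges Ascending step-length breakpoints in meters; the k-th
#'   zone is `[zone_edges[k], zone_edges[k+1])` (last zone closed).
#' @param coefficients One positive multiplier per zone
#'   (`length(zone_edges) - 1` of them).
#' @param condition Which walking condition the table was fit on:
#'   `"all"`, `"normal"` or `"dual_task"`.
#' @param flagged Optional logical per zone: `TRUE` marks zones that
#'   inherited a neighbour's coefficient during fitting (too few pairs).
#' @return A `coefficient_table` object.
#' @export
coefficient_table <- function(zone_edges, coefficients,
                              condition = c("all", "normal", "dual_task"),
                              flagged = NULL) {
  condition <- match.arg(condition)
  if (length(zone_edges) < 2 || any(diff(zone_edges) <= 0)) {
    stop_input("zone_edges must be at least 2 strictly increasing breakpoints")
  }
  if (length(coefficients) != length(zone_edges) - 1) {
    stop_input("need exactly %d coefficients for %d edges",
               length(zone_edges) - 1, length(zone_edges))
  }
  if (any(!is.finite(coefficients)) || any(coefficients <= 0)) {
    stop_input("coefficients must be positive and finite")
  }
  if (is.null(flagged)) flagged <- rep(FALSE, length(coefficients))
  structure(list(zone_edges = as.numeric(zone_edges),
                 coefficients = as.numeric(coefficients),
                 condition = condition,
                 flagged = as.logical(flagged)),
            class = "coefficient_table")
}

#' @export
print.coefficient_table <- function(x, ...) {
  nz <- length(x$coefficients)
  cat(sprintf("Zone coefficients (%s condition):\n", x$condition))
  for (k in seq_len(nz)) {
    cat(sprintf("  [%.2f, %.2f%s m: %.4f%s\n",
                x$zone_edges[k], x$zone_edges[k + 1],
                if (k == nz) "]" else ")",
                x$coefficients[k],
                if (x$flagged[k]) "  (inherited)" else ""))
  }
  invisible(x)
}

#' Built-in zone coefficients
#'
#' The package's built-in correction tables on the zone grid
#' 0.2 / 0.5 / 0.8 / 1.1 m: one fit on all calibration data, one on normal
#' walking only, one on dual-task walking only.
#'
#' @param condition `"all"` (1.37, 1.02, 0.74), `"normal"`
#'   (1.40, 1.04, 0.74) or `"dual_task"` (1.36, 1.01, 0.73).
#' @return A [coefficient_table()].
#' @export
default_coefficients <- function(condition = c("all", "normal", "dual_task")) {
  condition <- match.arg(condition)
  coeffs <- switch(condition,
    all = c(1.37, 1.02, 0.74),
    normal = c(1.40, 1.04, 0.74),
    dual_task = c(1.36, 1.01, 0.73)
  )
  coefficient_table(c(0.2, 0.5, 0.8, 1.1), coeffs, condition)
}

## Zone index of step lengths x under a coefficient table; values outside
## the edge span are clamped to the nearest zone.
zone_index <- function(x, coeffs) {
  edges <- coeffs$zone_edges
  z <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(z, 1L), length(coeffs$coefficients))
}

#' Apply the zone-coefficient step-length correction
#'
#' Adjusted step length = coefficient(zone of the raw estimate) x raw
#' estimate. Zone membership uses the ORIGINAL (raw) estimate. Inputs
#' outside the edge span use the nearest zone's coefficient and are
#' flagged `out_of_range`.
#'
#' @param step_length Raw step length(s), m, positive.
#' @param coeffs A [coefficient_table()].
#' @return Data frame with columns `adjusted` (m), `zone` (integer) and
#'   `out_of_range` (logical), one row per input.
#' @examples
#' apply_adjustment(0.60, default_coefficients("all"))  # 0.612 m, zone 2
#' @export
apply_adjustment <- function(step_length, coeffs) {
  if (!inherits(coeffs, "coefficient_table")) stop_input("coeffs must be a coefficient_table")
  if (any(!is.finite(step_length)) || any(step_length <= 0)) {
    stop_input("step lengths must be positive and finite")
  }
  z <- zone_index(step_length, coeffs)
  edges <- coeffs$zone_edges
  oor <- step_length < edges[1] | step_length > edges[length(edges)]
  data.frame(adjusted = coeffs$coefficients[z] * step_length,
             zone = z, out_of_range = oor)
}

#' Fill the adjusted columns of a stride table
#'
#' Applies [apply_adjustment()] to both step lengths of every stride and
#' recomputes gait speed from the adjusted stride length through the same
#' speed formula (never by scaling speed directly).
#'
#' @param table A `stride_table` from [estimate_gait()].
#' @param coeffs A [coefficient_table()].
#' @return The table with `step_length_adj_1_m`, `step_length_adj_2_m`,
#'   `zone_1`, `zone_2` and `speed_adj_mps` filled.
#' @export
adjust_stride_table <- function(table, coeffs) {
  if (!is.data.frame(table) || nrow(table) == 0) stop_input("empty stride table")
  a1 <- apply_adjustment(table$step_length_1_m, coeffs)
  a2 <- apply_adjustment(table$step_length_2_m, coeffs)
  table$step_length_adj_1_m <- a1$adjusted
  table$step_length_adj_2_m <- a2$adjusted
  table$zone_1 <- a1$zone
  table$zone_2 <- a2$zone
  table$speed_adj_mps <- (a1$adjusted + a2$adjusted) / table$stride_time_s
  table
}

#' Fit zone coefficients from paired app/reference step lengths
#'
#' Lays a zone grid of the given width (anchored at `anchor`) over the
#' observed range of app estimates and sets each zone's coefficient to
#' mean(reference) / mean(estimate) over the pairs whose ESTIMATE falls in
#' the zone. The ratio-of-means estimator is 1 under no bias and equals
#' the through-origin least-squares slope under homoscedastic
#' multiplicative error. Zones with fewer than 2 pairs inherit the nearest
#' populated zone's coefficient and are flagged.
#'
#' @param paired A [paired_steps()] data frame (columns `est`, `ref`).
#' @param width Zone width in meters.
#' @param anchor Grid anchor in meters (default 0.2; edges sit at
#'   `anchor + k * width`).
#' @param condition Condition label stored in the result.
#' @return A [coefficient_table()].
#' @export
fit_zone_coefficients <- function(paired, width, anchor = 0.2,
                                  condition = "all") {
  if (!is.data.frame(paired) || nrow(paired) == 0) stop_input("empty paired set")
  if (width <= 0) stop_input("width must be positive")
  est <- paired$est
  ref <- paired$ref
  k_lo <- floor((min(est) - anchor) / width)
  k_hi <- ceiling((max(est) - anchor) / width)
  if (k_hi <= k_lo) k_hi <- k_lo + 1
  edges <- anchor + (k_lo:k_hi) * width
  nz <- length(edges) - 1
  z <- findInterval(est, edges, rightmost.closed = TRUE)
  z <- pmin(pmax(z, 1L), nz)
  counts <- tabulate(z, nbins = nz)
  coeffs <- rep(NA_real_, nz)
  for (j in which(counts >= 2)) {
    coeffs[j] <- mean(ref[z == j]) / mean(est[z == j])
  }
  populated <- which(!is.na(coeffs))
  if (length(populated) == 0) {
    stop_compute("no zone holds at least 2 pairs; cannot fit coefficients")
  }
  flagged <- is.na(coeffs)
  for (j in which(flagged)) {
    nearest <- populated[which.min(abs(populated - j))]
    coeffs[j] <- coeffs[nearest]
  }
  coefficient_table(edges, coeffs, condition, flagged = flagged)
}

#' Search zone-interval widths for the best-calibrating grid
#'
#' For each candidate width: fit zone coefficients on the paired data,
#' adjust the estimates, and regress adjusted-vs-reference with
#' Passing-Bablok orthogonal regression. The selected width minimizes
#' |slope - 1|, with ties broken by smaller |intercept|, then by smaller
#' width. The whole search is a deterministic function of its inputs.
#'
#' @param paired A [paired_steps()] data frame.
#' @param widths Candidate widths in meters
#'   (default `seq(0.10, 0.50, by = 0.05)`).
#' @param anchor Zone-grid anchor, m (default 0.2, shared by all widths).
#' @return An `interval_search` object: list with `table` (data frame
#'   `width, slope, intercept`), `selected_width`, and `coefficients`
#'   (the fitted [coefficient_table()] at the selected width).
#' @export
select_interval <- function(paired, widths = seq(0.10, 0.50, by = 0.05),
                            anchor = 0.2) {
  if (length(widths) == 0) stop_input("widths must be non-empty")
  widths <- sort(widths)
  fits <- lapply(widths, function(w) fit_zone_coefficients(paired, w, anchor))
  rows <- mapply(function(w, ct) {
    adj <- apply_adjustment(paired$est, ct)$adjusted
    pb <- passing_bablok(paired$ref, adj)
    c(width = w, slope = pb$slope, intercept = pb$intercept)
  }, widths, fits)
  tab <- as.data.frame(t(rows))
  ## lexicographic selection: |slope-1|, then |intercept|, then width
  ord <- order(abs(tab$slope - 1), abs(tab$intercept), tab$width)
  best <- ord[1]
  structure(list(table = tab,
                 selected_width = tab$width[best],
                 coefficients = fits[[best]]),
            class = "interval_search")
}

#' @export
print.interval_search <- function(x, ...) {
  cat("Zone-interval search (Passing-Bablok slope/intercept per width):\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  width %.2f m: slope %6.3f, intercept %+7.3f m%s\n",
                tab$width[i], tab$slope[i], tab$intercept[i],
                if (tab$width[i] == x$selected_width) "   <- selected" else ""))
  }
  invisible(x)
}

#' Write a coefficient table to a YAML config file
#'
#' @param coeffs A [coefficient_table()].
#' @param path Output path.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "coefficient_table"))
  yaml::write_yaml(list(zone_edges = coeffs$zone_edges,
                        coefficients = coeffs$coefficients,
                        condition = coeffs$condition), path)
  invisible(path)
}

#' Read a coefficient table from a YAML config file
#'
#' @param path Path to a file written by [write_coefficients()].
#' @return A [coefficient_table()].
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$zone_edges) || is.null(y$coefficients)) {
    stop_input("coefficient file must define zone_edges and coefficients")
  }
  coefficient_table(as.numeric(y$zone_edges), as.numeric(y$coefficients),
                    condition = if (is.null(y$condition)) "all" else y$condition)
}
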