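## Reading, validating and writing trial data.
##
## File dialect (fixed): comma-separated, dot decimal, mandatory header row.
## IMU channels are SI throughout: accelerometer m/s^2, gyroscope rad/s,
## time in seconds since trial start. Phones whose API reports acceleration
## in g-units are handled by `accel_in_g = TRUE` (conversion by 9.80665).

IMU_REQUIRED_COLS <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
IMU_MAG_COLS <- c("mx", "my", "mz")

STRIDE_TABLE_COLS <- c(
  "stride_index", "t_start_s", "stride_time_s", "h1_m", "h2_m",
  "step_length_1_m", "step_length_2_m",
  "step_length_adj_1_m", "step_length_adj_2_m", "zone_1", "zone_2",
  "stride_length_m", "speed_mps", "speed_adj_mps"
)

#' Construct a validated IMU trial recording
#'
#' Bundles the channel data frame with subject metadata and checks the
#' contract every downstream operation relies on: monotone time at the
#' nominal rate, at least 2 s of data, finite values only, and a plausible
#' leg length.
#'
#' @param data Data frame with columns `t, ax, ay, az, gx, gy, gz` and
#'   optionally `mx, my, mz`. Units: s, m/s^2, rad/s.
#' @param fs Nominal sampling frequency in Hz (the app records at 100 Hz).
#' @param subject_id Subject label.
#' @param leg_length Leg length in meters; must lie in (0.5, 1.4).
#'   The pendulum model needs it; `NA` is allowed for recordings used only
#'   for event detection.
#' @param condition Walking condition: `"normal"`, `"dual_task"` or
#'   `"unknown"`.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(data, fs = 100, subject_id = "unknown",
                          leg_length = NA_real_,
                          condition = c("unknown", "normal", "dual_task")) {
  condition <- match.arg(condition)
  if (!is.data.frame(data)) stop_input("data must be a data frame")
  missing_cols <- setdiff(IMU_REQUIRED_COLS, names(data))
  if (length(missing_cols) > 0) {
    stop_input("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (fs <= 0) stop_input("fs must be positive")
  if (!is.na(leg_length) && (leg_length <= 0.5 || leg_length >= 1.4)) {
    stop_input("leg_length must lie in (0.5, 1.4) m, got %g", leg_length)
  }
  keep <- intersect(c(IMU_REQUIRED_COLS, IMU_MAG_COLS), names(data))
  data <- data[, keep, drop = FALSE]

  ## Drop rows with non-finite values (never interpolate: the integration
  ## path is gap-sensitive). Gaps longer than 3 consecutive samples abort.
  finite_row <- rowSums(!is.finite(as.matrix(data))) == 0
  dropped <- sum(!finite_row)
  if (dropped > 0) {
    runs <- rle(!finite_row)
    if (any(runs$lengths[runs$values] > 3)) {
      stop_input("gap of more than 3 consecutive invalid samples; recording unusable")
    }
    data <- data[finite_row, , drop = FALSE]
    rownames(data) <- NULL
    message(sprintf("imu_recording: dropped %d row(s) with non-finite values", dropped))
  }

  n <- nrow(data)
  if (n < 2 * fs) {
    stop_input("recording too short: %d samples (< 2 s at %g Hz)", n, fs)
  }
  dt <- diff(data$t)
  if (any(dt <= 0)) stop_input("time column must be strictly increasing")
  med_dt <- median(dt)
  if (abs(med_dt - 1 / fs) > 0.05 / fs) {
    stop_input("median sampling interval %g s deviates > 5%% from nominal 1/fs = %g s",
               med_dt, 1 / fs)
  }

  structure(
    list(data = data, fs = fs, subject_id = subject_id,
         leg_length = leg_length, condition = condition,
         n_dropped = dropped),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "IMU recording: subject %s, %d samples at %g Hz (%.1f s), condition %s\n",
    x$subject_id, nrow(x$data), x$fs, nrow(x$data) / x$fs, x$condition))
  if (!is.na(x$leg_length)) cat(sprintf("  leg length: %.3f m\n", x$leg_length))
  if (x$n_dropped > 0) cat(sprintf("  dropped rows at ingest: %d\n", x$n_dropped))
  invisible(x)
}

#' Read an IMU trial recording from CSV
#'
#' Expects columns `t,ax,ay,az,gx,gy,gz` (magnetometer `mx,my,mz` optional),
#' comma-separated with a header row. Rows containing non-finite values are
#' dropped and counted; sample order is never changed.
#'
#' @param path Path to the CSV file.
#' @param fs Nominal sampling frequency in Hz.
#' @param subject_id,leg_length,condition Subject metadata,
#'   see [imu_recording()].
#' @param accel_in_g If `TRUE`, accelerometer columns are interpreted as
#'   g-units and converted to m/s^2 by 9.80665.
#' @return An [imu_recording()] object.
#' @export
read_imu_csv <- function(path, fs = 100, subject_id = "unknown",
                         leg_length = NA_real_, condition = "unknown",
                         accel_in_g = FALSE) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (accel_in_g) {
    for (col in c("ax", "ay", "az")) {
      if (col %in% names(df)) df[[col]] <- df[[col]] * 9.80665
    }
  }
  imu_recording(df, fs = fs, subject_id = subject_id,
                leg_length = leg_length, condition = condition)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_imu_csv()]: channel values round-trip bit-identically
#' (full precision, dot decimal).
#'
#' @param rec An [imu_recording()].
#' @param path Output path.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- rec$data
  df[] <- lapply(df, function(col) format(col, digits = 17, trim = TRUE, scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference step-length table
#'
#' Reads an instrumented-walkway-style export with columns
#' `step_index,step_length_ref[,stride_time_ref]` (meters, seconds). Rows are
#' ordered by `step_index`; non-positive step lengths are rejected.
#'
#' @param path Path to the CSV file.
#' @param source Text label describing the reference system.
#' @return Data frame of class `reference_steps`.
#' @export
read_reference_csv <- function(path, source = "reference") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"step_length_ref" %in% names(df)) {
    stop_input("missing mandatory column: step_length_ref")
  }
  if (!"step_index" %in% names(df)) df$step_index <- seq_len(nrow(df))
  if (any(!is.finite(df$step_length_ref)) || any(df$step_length_ref <= 0)) {
    stop_input("step_length_ref must be positive and finite")
  }
  df <- df[order(df$step_index), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source") <- source
  class(df) <- c("reference_steps", "data.frame")
  df
}

#' Write a per-stride gait table to CSV
#'
#' Writes the stride table produced by [estimate_gait()] with the fixed
#' column set (see Details), floats at 6 significant digits.
#'
#' @details Columns: `r paste(STRIDE_TABLE_COLS, collapse = ", ")`.
#' @param table A `stride_table` (or compatible data frame).
#' @param path Output path.
#' @export
write_stride_table <- function(table, path) {
  if (!is.data.frame(table)) stop_input("table must be a data frame")
  if (nrow(table) == 0) stop_input("refusing to write an empty stride table")
  missing_cols <- setdiff(STRIDE_TABLE_COLS, names(table))
  if (length(missing_cols) > 0) {
    stop_input("stride table missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  out <- table[, STRIDE_TABLE_COLS, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("stride_index", "zone_1", "zone_2"))
  out[num] <- lapply(out[num], function(col) signif(col, 6))
  ok <- tryCatch({ write.csv(out, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_input("cannot write stride table to %s", path)
  invisible(path)
}

#' Read a per-stride gait table from CSV
#'
#' @param path Path to a file written by [write_stride_table()].
#' @return A `stride_table` data frame.
#' @export
read_stride_table <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STRIDE_TABLE_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop_input("stride table missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  class(df) <- c("stride_table", "data.frame")
  df
}

#' Read a paired app-vs-reference step-length table
#'
#' Columns `est,ref` in meters: `est` the app-derived step length, `ref`
#' the reference-system step length for the same step.
#'
#' @param path Path to the CSV file.
#' @return A `paired_steps` data frame.
#' @export
read_paired_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("est", "ref"), names(df))
  if (length(missing_cols) > 0) {
    stop_input("paired table missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  paired_steps(df$est, df$ref)
}

#' Construct a paired step-length set
#'
#' @param est App-estimated step lengths (m).
#' @param ref Reference step lengths (m), same length and order.
#' @return A `paired_steps` data frame.
#' @export
paired_steps <- function(est, ref) {
  if (length(est) != length(ref)) stop_input("est and ref must have equal length")
  if (length(est) < 2) stop_input("need at least 2 pairs")
  if (any(!is.finite(est)) || any(!is.finite(ref)) ||
      any(est <= 0) || any(ref <= 0)) {
    stop_input("paired step lengths must be positive and finite")
  }
  structure(data.frame(est = est, ref = ref),
            class = c("paired_steps", "data.frame"))
}
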