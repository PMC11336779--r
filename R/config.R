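## Pipeline configuration: a nested list with documented defaults,
## serializable as flat dotted keys in YAML (e.g. `events.lp_cutoff_hz: 3`).

#' Default pipeline configuration
#'
#' @return Nested list of pipeline parameters:
#' \describe{
#'   \item{orientation.method}{`"tilt_complementary"` or `"gyro_only"`.}
#'   \item{orientation.gain}{Complementary-filter gain per sample (0.02).}
#'   \item{gravity_mps2}{Gravity subtracted after rotation (9.80665).}
#'   \item{events.lp_cutoff_hz}{Event-detection low-pass cutoff (3 Hz).}
#'   \item{events.min_period_s}{Heel-strike refractory period (0.4 s).}
#'   \item{events.prominence_k}{Peak-prominence threshold in robust-SD
#'     units (1.0).}
#'   \item{events.stride_gate_s}{Admissible stride duration (0.5-2.5 s).}
#'   \item{pendulum.hp_cutoff_hz}{Drift-removal high-pass cutoff (0.11 Hz).}
#'   \item{pendulum.hp_order}{Drift-removal filter order (4).}
#' }
#' @export
default_config <- function() {
  list(
    orientation = list(method = "tilt_complementary", gain = 0.02),
    gravity_mps2 = 9.80665,
    events = list(lp_cutoff_hz = 3, min_period_s = 0.4, prominence_k = 1.0,
                  stride_gate_s = c(0.5, 2.5)),
    pendulum = list(hp_cutoff_hz = 0.11, hp_order = 4)
  )
}

## Recursive merge of user values over defaults; unknown keys rejected.
merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML file with either nested sections or flat dotted keys
#' (`events.lp_cutoff_hz: 2.5`). Values merge over [default_config()];
#' unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) return(default_config())
  nested <- list()
  for (nm in names(y)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      nested[[nm]] <- y[[nm]]
    } else if (length(parts) == 2) {
      if (is.null(nested[[parts[1]]])) nested[[parts[1]]] <- list()
      nested[[parts[1]]][[parts[2]]] <- y[[nm]]
    } else {
      stop_input("config key too deep: %s", nm)
    }
  }
  merge_config(default_config(), nested)
}
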