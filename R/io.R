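# CSV / YAML / JSON interfaces.
#
# CSV dialect: UTF-8, comma-separated, header row, ISO-8601 timestamps,
# empty cells for missing values. Timestamps are naive local time (the
# study design is single-timezone).

#' Read an EMA response CSV
#'
#' Expected columns: `participant_id`, `timestamp` (ISO-8601), `item1` ..
#' `item9`, `trap`, `duration_s`.
#'
#' @param path file path.
#' @return data.table of EMA responses.
#' @export
read_ema_csv <- function(path) {
  dt <- data.table::fread(path)
  check_columns(dt, c("participant_id", "timestamp", item_cols(), "trap",
                      "duration_s"), sprintf("EMA CSV '%s'", path))
  dt[, "timestamp" := as.POSIXct(dt$timestamp, tz = "",
                                 tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                "%Y-%m-%d %H:%M:%S"))]
  dt[]
}

#' Read a long-format sensor record CSV
#'
#' Expected columns: `participant_id`, `source`, `timestamp`, `field`,
#' `value`; GPS rows carry their coordinates in `lat` / `lon` columns, and
#' categorical detail (call direction, app label, activity type) rides in
#' `tag`.
#'
#' @param path file path.
#' @return data.table of sensor records.
#' @export
read_sensor_csv <- function(path) {
  dt <- data.table::fread(path)
  check_columns(dt, c("participant_id", "source", "timestamp", "field",
                      "value"), sprintf("sensor CSV '%s'", path))
  dt[, "timestamp" := as.POSIXct(dt$timestamp, tz = "",
                                 tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                "%Y-%m-%d %H:%M:%S"))]
  for (col in c("tag", "lat", "lon")) {
    if (!col %in% names(dt)) {
      data.table::set(dt, j = col,
                      value = if (col == "tag") NA_character_ else NA_real_)
    }
  }
  if (!"record_id" %in% names(dt)) dt[, "record_id" := seq_len(.N)]
  dt[]
}

#' Read a demographics CSV
#'
#' Expected columns: `participant_id`, `gender`, `age`.
#'
#' @param path file path.
#' @return data.table.
#' @export
read_demographics_csv <- function(path) {
  dt <- data.table::fread(path)
  check_columns(dt, c("participant_id", "gender", "age"),
                sprintf("demographics CSV '%s'", path))
  dt[]
}

#' Write a synthetic cohort bundle to CSV files
#'
#' Writes `ema.csv`, `sensors.csv` and `demographics.csv` in the same
#' dialects the pipeline readers expect.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_cohort_csv <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ema = file.path(dir, "ema.csv"),
    sensors = file.path(dir, "sensors.csv"),
    demographics = file.path(dir, "demographics.csv")
  )
  data.table::fwrite(bundle$ema, paths["ema"], dateTimeAs = "write.csv")
  data.table::fwrite(bundle$sensors, paths["sensors"],
                     dateTimeAs = "write.csv")
  data.table::fwrite(bundle$demographics, paths["demographics"])
  invisible(paths)
}

RUN_CONFIG_DEFAULTS <- list(
  platform = "android",
  seed = 1L,
  # simulator block (used when no input CSVs are given)
  n_participants = 20L,
  n_days = 90L,
  # input files (optional; override the simulator)
  ema_csv = NULL,
  sensor_csv = NULL,
  demographics_csv = NULL,
  out_dir = NULL,
  # stage thresholds, at their published defaults
  speeder_fraction = 0.10,
  dbscan_eps = 0.0005,
  min_stay_h = 2.5,
  var_threshold = 0.05,
  miss_threshold = 0.20,
  month_days = 30L,
  models = SEVERITY_MODELS,
  weighted_sp = FALSE
)

#' Build a validated run configuration
#'
#' All stage thresholds carry their published defaults (speeder fraction
#' 0.10, DBSCAN epsilon 0.0005 degrees, 2.5 h minimum stay, quasi-constant
#' variance threshold 0.05, 20% missingness threshold, 30-day profiling
#' month). Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown) > 0L) {
    stop_config("run_config: unknown configuration key(s): %s",
                paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, over)
  if (!cfg$platform %in% c("android", "ios")) {
    stop_config("run_config: platform must be 'android' or 'ios'")
  }
  if (!all(cfg$models %in% SEVERITY_MODELS)) {
    stop_config("run_config: models must be a subset of: %s",
                paste(SEVERITY_MODELS, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file of key-value pairs; keys must be known
#'   configuration fields.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
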