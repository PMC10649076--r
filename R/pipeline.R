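# End-to-end pipeline driver: simulate (or load) -> EMA processing ->
# sensor processing -> first-month split -> symptom probability models ->
# SS/SH/SP construction -> LOSO severity classification with both input
# representations -> comparison and group summaries, with a run manifest
# reconciling record counts across stages.

#' Run the full symptom-profiling pipeline
#'
#' Executes the stages in their fixed order and returns every intermediate
#' product plus a run manifest. Inputs come either from the configured CSV
#' paths or, when none are given, from the seeded synthetic cohort
#' simulator. If `config$out_dir` is set, stage outputs are written there
#' as CSV/JSON.
#'
#' @param config a `run_config`.
#' @param cohort optional `cohort_bundle` to use instead of files or a
#'   fresh simulation.
#' @return list of stage outputs with classes attached; see the manifest
#'   entry `counts` for per-stage record accounting.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  checksums <- list()

  # ---- inputs ---------------------------------------------------------
  if (is.null(cohort) && !is.null(config$ema_csv)) {
    ema <- read_ema_csv(config$ema_csv)
    sensors <- read_sensor_csv(config$sensor_csv)
    demographics <- read_demographics_csv(config$demographics_csv)
    checksums <- as.list(tools::md5sum(c(config$ema_csv, config$sensor_csv,
                                         config$demographics_csv)))
  } else {
    if (is.null(cohort)) {
      cohort <- simulate_cohort(simulation_config(
        n_participants = config$n_participants, n_days = config$n_days,
        platform = config$platform, seed = config$seed))
    }
    ema <- cohort$ema
    sensors <- cohort$sensors
    demographics <- cohort$demographics
  }

  # ---- EMA pipeline ---------------------------------------------------
  ema_out <- process_ema(ema, speeder_fraction = config$speeder_fraction)

  # ---- sensor pipeline ------------------------------------------------
  sens_out <- process_sensors(
    sensors, demographics, platform = config$platform,
    eps = config$dbscan_eps, min_stay_h = config$min_stay_h,
    var_threshold = config$var_threshold,
    miss_threshold = config$miss_threshold)

  # ---- first-month split ---------------------------------------------
  split_daily <- split_first_month(ema_out$daily, config$month_days)
  split_feat <- split_first_month(sens_out$features, config$month_days)

  # ---- symptom significance, probability models, profiles -------------
  ss <- compute_symptom_significance(split_daily$profile)
  model_set <- train_symptom_models(split_feat$profile, split_daily$profile,
                                    seed = config$seed)
  sh <- predict_symptom_probabilities(model_set, split_feat$prediction)
  sp <- compose_symptom_profile(sh, ss)
  sp_input <- if (isTRUE(config$weighted_sp)) {
    apply_symptom_weights(sp)
  } else {
    sp
  }

  # ---- severity classification: sensor vs symptom-profile input -------
  sensor_ds <- severity_dataset(split_feat$prediction, split_daily$prediction)
  sp_ds <- severity_dataset(sp_input, split_daily$prediction)
  # restrict both representations to their common participant-day universe
  common <- sensor_ds$keys[sp_ds$keys, on = c("participant_id", "date"),
                           nomatch = NULL, which = TRUE]
  if (length(common) < nrow(sensor_ds$keys)) {
    keep_keys <- sensor_ds$keys[sort(common)]
    sensor_ds <- restrict_dataset(sensor_ds, keep_keys)
    sp_ds <- restrict_dataset(sp_ds, keep_keys)
  }
  comparison <- compare_input_representations(
    sensor_ds, sp_ds, models = config$models, seed = config$seed,
    sp_feature_weights = NULL)
  baseline <- majority_class_baseline(sp_ds$y)
  summary_tab <- summarize_group_profiles(sp, split_daily$prediction)

  manifest <- structure(list(
    config = unclass(config),
    package_version = as.character(packageVersion("symprof")),
    seed = config$seed,
    input_checksums = checksums,
    counts = list(
      ema = ema_out$counts,
      sensors = sens_out$counts,
      participants_excluded_split = length(split_daily$excluded),
      month1_days = nrow(split_daily$profile),
      prediction_days = nrow(split_daily$prediction),
      severity_rows = length(sp_ds$y)
    ),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_manifest")

  result <- list(
    manifest = manifest,
    daily = ema_out$daily,
    observed = ema_out$observed,
    features = sens_out$features,
    boxcox_params = sens_out$boxcox_params,
    split = list(daily = split_daily, features = split_feat),
    ss = ss,
    model_set = model_set,
    sh = sh,
    sp = sp,
    comparison = comparison,
    baseline = baseline,
    group_profiles = summary_tab
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

restrict_dataset <- function(ds, keep_keys) {
  idx <- ds$keys[keep_keys, on = c("participant_id", "date"), which = TRUE]
  list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
       keys = ds$keys[idx], participants = ds$participants[idx])
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(result$daily, file.path(out_dir, "daily_symptoms.csv"))
  data.table::fwrite(result$features, file.path(out_dir, "features.csv"))
  data.table::fwrite(result$ss, file.path(out_dir, "symptom_significance.csv"))
  data.table::fwrite(result$sh, file.path(out_dir, "symptom_probabilities.csv"))
  data.table::fwrite(result$sp, file.path(out_dir, "symptom_profiles.csv"))
  data.table::fwrite(result$group_profiles,
                     file.path(out_dir, "group_profiles.csv"))
  data.table::fwrite(result$comparison$table,
                     file.path(out_dir, "comparison.csv"))
  jsonlite::write_json(
    list(comparison = result$comparison$table,
         averages = result$comparison$averages,
         baseline = list(weighted = result$baseline$weighted,
                         majority = result$baseline$majority),
         manifest = result$manifest[c("seed", "package_version", "counts",
                                      "runtime_s")]),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("symprof run manifest (package %s, seed %d, %.1f s)\n",
              x$package_version, x$seed, x$runtime_s))
  c1 <- x$counts$ema
  cat(sprintf("  EMA: %d responses -> %d kept (%d trap-discarded, %d speeder-discarded), %d observed days, %d dense days\n",
              c1$input, c1$kept, c1$reliability_discarded,
              c1$speeder_discarded, c1$observed_days, c1$dense_days))
  c2 <- x$counts$sensors
  cat(sprintf("  sensors: %d records, %d out-of-range removed, %d GPS noise removed, %d imputed\n",
              c2$input, c2$out_of_range_removed, c2$gps_noise_removed,
              c2$imputed_rows))
  cat(sprintf("  split: %d month-1 days, %d prediction days (%d participants excluded), %d severity rows\n",
              x$counts$month1_days, x$counts$prediction_days,
              x$counts$participants_excluded_split, x$counts$severity_rows))
  invisible(x)
}
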