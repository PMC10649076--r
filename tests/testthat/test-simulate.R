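# Synthetic cohort simulator: determinism, group assignment, EMA schedule,
# planted artefacts, sensor cadences and latent-to-sensor coupling.

small_cfg <- function(...) {
  simulation_config(n_participants = 5, n_days = 36, seed = 123, ...)
}

test_that("identical configuration and seed reproduce the bundle exactly", {
  b1 <- simulate_cohort(small_cfg())
  b2 <- simulate_cohort(small_cfg())
  expect_identical(b1$demographics, b2$demographics)
  expect_identical(b1$latent, b2$latent)
  expect_identical(b1$ema, b2$ema)
  expect_identical(b1$sensors, b2$sensors)
  expect_identical(b1$truth, b2$truth)
  # a different seed changes the draws
  b3 <- simulate_cohort(simulation_config(n_participants = 5, n_days = 36,
                                          seed = 124))
  expect_false(identical(b1$ema$duration_s, b3$ema$duration_s))
})

test_that("rounding-free severity fractions give exact group counts", {
  cfg <- simulation_config(n_participants = 10, n_days = 31,
                           severity_group_fractions = c(0.5, 0.3, 0.2),
                           seed = 1)
  b <- simulate_cohort(cfg)
  counts <- table(b$demographics$severity_group)
  expect_equal(counts[["none_mild"]], 5L)
  expect_equal(counts[["moderate"]], 3L)
  expect_equal(counts[["severe"]], 2L)
  # all three age bands populated by construction
  expect_setequal(unique(b$demographics$age_group),
                  c("<=30", "31-45", ">=46"))
})

test_that("a degenerate AR(1) pins the latent intensities at the group means", {
  cfg <- simulation_config(n_participants = 6, n_days = 31,
                           symptom_ar_coefficient = 0,
                           symptom_noise_sd = 1e-9, seed = 5)
  b <- simulate_cohort(cfg)
  mu <- c(none_mild = 0.50, moderate = 1.55, severe = 2.40)
  expected <- unname(mu[b$demographics$severity_group[
    match(b$latent$participant_id, b$demographics$participant_id)]])
  for (j in 1:9) {
    expect_equal(b$latent[[paste0("i", j)]], expected, tolerance = 1e-6)
  }
})

test_that("EMA responses fall only on scheduled days and slots, 30 per participant at 90/3", {
  cfg <- simulation_config(n_participants = 3, n_days = 90, seed = 9)
  b <- simulate_cohort(cfg)
  per <- table(b$ema$participant_id)
  expect_true(all(per == 30 * 3))         # 30 scheduled days x 3 slots
  day_idx <- as.integer(as.Date(b$ema$timestamp) - cfg$start_date) + 1L
  expect_true(all((day_idx - 1L) %% 3L == 0L))
  expect_true(all(format(b$ema$timestamp, "%H:%M") %in%
                    c("10:00", "14:00", "18:00")))
  expect_true(all(as.matrix(b$ema[, paste0("item", 1:9), with = FALSE])
                  %in% 0:3))
})

test_that("zero planted error rates mean the filters find nothing to discard", {
  cfg <- simulation_config(n_participants = 4, n_days = 36,
                           trap_error_fraction = 0, speeder_fraction = 0,
                           sensor_outlier_rate = 0, seed = 21)
  b <- simulate_cohort(cfg)
  expect_length(b$truth$trap_errors, 0)
  expect_equal(nrow(filter_reliability(b$ema)$discarded), 0L)
  expect_length(b$truth$gps_outliers, 0)
  expect_length(b$truth$negative_durations, 0)
  expect_equal(nrow(remove_out_of_range(b$sensors)$removed), 0L)
})

test_that("planted speeders are the responses the speeder filter voids", {
  cfg <- simulation_config(n_participants = 12, n_days = 90,
                           speeder_fraction = 0.10,
                           trap_error_fraction = 0, seed = 33)
  b <- simulate_cohort(cfg)
  idx <- compute_speeder_index(b$ema)
  out <- filter_speeders(idx, 0.10)
  n <- nrow(b$ema)
  planted <- b$truth$speeders
  # about 10% voided at the 10% threshold, and they are the planted ones
  expect_lt(abs(nrow(out$discarded) - length(planted)) / n, 0.02)
  # the voided set is essentially the planted set; the empirical decile
  # boundary can graze a few genuinely slow-but-honest responses
  expect_gt(mean(out$discarded$response_id %in% planted), 0.90)
  expect_gt(mean(planted %in% out$discarded$response_id), 0.90)
})

test_that("planted trap errors differ from item 2 by at least two points", {
  cfg <- simulation_config(n_participants = 8, n_days = 45,
                           trap_error_fraction = 0.2, seed = 13)
  b <- simulate_cohort(cfg)
  bad <- b$ema[b$ema$response_id %in% b$truth$trap_errors]
  good <- b$ema[!b$ema$response_id %in% b$truth$trap_errors]
  expect_true(all(abs(bad$item2 - bad$trap) >= 2))
  expect_true(all(good$item2 == good$trap))
  expect_equal(nrow(filter_reliability(b$ema)$discarded), nrow(bad))
})

test_that("GPS runs at its 15-minute cadence: 96 points per day without missing spans", {
  cfg <- simulation_config(n_participants = 2, n_days = 31,
                           sensor_missing_rate = 0, sensor_outlier_rate = 0,
                           seed = 2)
  b <- simulate_cohort(cfg)
  gps <- b$sensors[b$sensors$source == "gps"]
  gps[, "date" := as.Date(timestamp)]
  per_day <- gps[, .N, by = c("participant_id", "date")]
  expect_true(all(per_day$N == 96L))
})

test_that("a zero loading matrix decouples event counts from the latent state", {
  sources <- unique(source_registry("android")$source)
  L0 <- matrix(0, 9, length(sources), dimnames = list(NULL, sources))
  cfg <- simulation_config(n_participants = 50, n_days = 90,
                           symptom_sensor_loading_matrix = L0,
                           participant_rate_sd = 0, seed = 77)
  b <- simulate_cohort(cfg)
  ped <- b$sensors[b$sensors$source == "pedometer"]
  ped[, "date" := as.Date(timestamp)]
  daily <- ped[, .N, by = c("participant_id", "date")]
  m <- b$latent[, c("participant_id", "date", "i4"), with = FALSE][
    daily, on = c("participant_id", "date")]
  expect_lt(abs(cor(m$i4, m$N)), 0.1)
})

test_that("a strong single loading is recoverable from the extracted daily feature", {
  sources <- unique(source_registry("ios")$source)
  L <- matrix(0, 9, length(sources), dimnames = list(NULL, sources))
  L[4, "pedometer"] <- 0.8
  cfg <- simulation_config(n_participants = 50, n_days = 90,
                           platform = "ios",
                           symptom_sensor_loading_matrix = L,
                           participant_rate_sd = 0,
                           sensor_outlier_rate = 0, seed = 41)
  b <- simulate_cohort(cfg)
  ped <- b$sensors[b$sensors$source == "pedometer"]
  ped[, "date" := as.Date(timestamp)]
  steps <- ped[, .(steps_n = sum(value)), by = c("participant_id", "date")]
  m <- b$latent[, c("participant_id", "date", "i4"), with = FALSE][
    steps, on = c("participant_id", "date")]
  expect_gt(cor(m$i4, m$steps_n), 0.5)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(5, n_days = 20), "n_days")
  expect_error(simulation_config(5, symptom_ar_coefficient = 1),
               "symptom_ar_coefficient")
  expect_error(simulation_config(5, severity_group_fractions = c(0.5, 0.5, 0.5)),
               "severity_group_fractions")
  expect_error(simulation_config(5, speeder_fraction = 1), "speeder_fraction")
  expect_error(simulation_config(5, symptom_noise_sd = 0), "symptom_noise_sd")
  expect_error(
    simulation_config(5, symptom_sensor_loading_matrix = matrix(0, 3, 3)),
    "loading_matrix")
  expect_error(simulation_config(5, symptom_effect_cap = -1),
               "symptom_effect_cap")
})

test_that("the ground-truth severity labels equal the bucketed latent totals", {
  b <- simulate_cohort(small_cfg())
  tot <- rowSums(as.matrix(b$latent[, paste0("i", 1:9), with = FALSE]))
  expect_equal(b$truth$severity_daily$latent_total, tot)
  expect_equal(as.character(b$truth$severity_daily$severity),
               as.character(classify_severity(tot)))
})
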