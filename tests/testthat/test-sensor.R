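# Sensor pipeline: range cleaning, DBSCAN GPS cleaning, gap imputation,
# Box-Cox transforms, daily features, location features, pruning.

gps_day <- function(lat, lon, participant = "P001",
                    date = as.Date("2021-07-05"), every_min = 15) {
  n <- length(lat)
  data.table::data.table(
    record_id = seq_len(n), participant_id = participant, source = "gps",
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = "") +
      (seq_len(n) - 1L) * every_min * 60,
    field = "location", value = NA_real_, tag = NA_character_,
    lat = lat, lon = lon)
}

test_that("range cleaning removes negative durations and impossible coordinates, keeps boundary values", {
  rec <- data.table::data.table(
    record_id = 1:4,
    participant_id = "P001",
    source = c("call_log", "pedometer", "gps", "gps"),
    timestamp = as.POSIXct("2021-07-01 10:00:00", tz = ""),
    field = c("duration_s", "steps", "location", "location"),
    value = c(-30, 0, NA, NA),
    tag = NA_character_,
    lat = c(NA, NA, 91, 37.5),
    lon = c(NA, NA, 127, 127))
  out <- remove_out_of_range(rec)
  expect_equal(out$removed$record_id, c(1L, 3L))   # negative call, 91 deg lat
  expect_equal(out$kept$record_id, c(2L, 4L))      # 0 steps is a valid count
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(rec))
  rec_bad <- data.table::copy(rec)[1, "source" := "teleport"]
  expect_error(remove_out_of_range(rec_bad), "teleport")
})

test_that("grid DBSCAN agrees with a brute-force oracle on random configurations", {
  set.seed(7)
  for (rep in 1:12) {
    k <- sample(1:3, 1)
    centers <- matrix(runif(2 * k, 0, 0.02), ncol = 2)
    n_per <- sample(5:40, k, replace = TRUE)
    x <- unlist(lapply(seq_len(k), function(i)
      centers[i, 1] + rnorm(n_per[i], 0, 2e-4)))
    y <- unlist(lapply(seq_len(k), function(i)
      centers[i, 2] + rnorm(n_per[i], 0, 2e-4)))
    # plus scattered noise points
    x <- c(x, runif(6, 0, 0.02))
    y <- c(y, runif(6, 0, 0.02))
    eps <- 5e-4
    min_pts <- sample(3:8, 1)
    got <- dbscan_points(x, y, eps, min_pts)
    want <- dbscan_brute(x, y, eps, min_pts)
    # noise sets must agree; cluster partitions up to core-point labelling
    expect_identical(got == 0L, want == 0L)
    core_agree <- mapply(function(a, b) a > 0 && b > 0, got, want)
    expect_true(same_clustering(got[core_agree], want[core_agree]))
  }
})

test_that("GPS cleaning removes a lone distant point but keeps a dense cluster intact", {
  pts <- gps_day(lat = c(rep(37.5, 96), 38.5),
                 lon = c(rep(127.0, 96), 127.0))
  pts$timestamp[97] <- pts$timestamp[96] + 60
  out <- clean_gps(pts)
  expect_equal(out$min_samples, 10L)  # ceil(2.5 h / 15 min)
  expect_equal(out$removed$record_id, 97L)
  expect_equal(nrow(out$kept), 96L)
  expect_true(all(out$kept$cluster == out$kept$cluster[1]))
  # all points within eps of a common centroid, n >= min_samples: none removed
  set.seed(1)
  tight <- gps_day(lat = 37.5 + runif(12, -2e-4, 2e-4),
                   lon = 127.0 + runif(12, -2e-4, 2e-4))
  expect_equal(nrow(clean_gps(tight)$removed), 0L)
  # fewer than min_samples points in total: everything flagged noise
  few <- gps_day(lat = rep(37.5, 5), lon = rep(127, 5))
  expect_warning(out_few <- clean_gps(few), "fewer than")
  expect_equal(nrow(out_few$kept), 0L)
})

test_that("gap imputation fills interval ticks linearly and leaves event streams untouched", {
  reg <- source_registry("android")
  base <- as.POSIXct("2021-07-01 10:00:00", tz = "")
  rec <- data.table::data.table(
    record_id = 1:2, participant_id = "P001", source = "light",
    timestamp = base + c(0, 1800), field = "lux", value = c(100, 200),
    tag = NA_character_, lat = NA_real_, lon = NA_real_)
  out <- impute_interval_gaps(rec, reg)
  expect_equal(nrow(out), 3L)
  mid <- out[out$imputed]
  expect_equal(mid$value, 150)                  # linear midpoint at t + 15 min
  expect_equal(mid$timestamp, base + 900)
  # event stream with a multi-day gap passes through unchanged
  ev <- data.table::data.table(
    record_id = 1:2, participant_id = "P001", source = "call_log",
    timestamp = base + c(0, 3 * 86400), field = "duration_s",
    value = c(60, 90), tag = "incoming", lat = NA_real_, lon = NA_real_)
  out_ev <- impute_interval_gaps(ev, reg)
  expect_equal(nrow(out_ev), 2L)
  expect_false(any(out_ev$imputed))
  # gap-free interval stream: identity
  dense <- data.table::data.table(
    record_id = 1:3, participant_id = "P001", source = "light",
    timestamp = base + c(0, 900, 1800), field = "lux", value = c(1, 2, 3),
    tag = NA_character_, lat = NA_real_, lon = NA_real_)
  expect_equal(nrow(impute_interval_gaps(dense, reg)), 3L)
})

test_that("Box-Cox reduces skewness, skips constant series, and never touches coordinates", {
  set.seed(99)
  base <- as.POSIXct("2021-07-01 00:00:00", tz = "")
  y <- rlnorm(1000, 3, 0.8)
  rec <- data.table::data.table(
    record_id = seq_len(1003), participant_id = "P001",
    source = c(rep("light", 1000), "screen", "screen", "screen"),
    timestamp = base + seq_len(1003) * 60,
    field = c(rep("lux", 1000), rep("duration_s", 3)),
    value = c(y, 5, 5, 5), tag = NA_character_,
    lat = NA_real_, lon = NA_real_)
  gps <- gps_day(lat = rep(37.5, 10), lon = rep(127, 10))
  out <- transform_boxcox(rbind(rec, gps, fill = TRUE))
  lux <- out$records[out$records$field == "lux"]
  expect_lt(abs(skewness(lux$value)), abs(skewness(y)))
  # constant series skipped and flagged
  scr <- out$records[out$records$field == "duration_s"]
  expect_equal(scr$value, c(5, 5, 5))
  prm <- out$params
  expect_true(prm$skipped[prm$source == "screen"])
  expect_false(prm$skipped[prm$source == "light"])
  # gps coordinates pass through untouched and are never fitted
  expect_equal(out$records[out$records$source == "gps"]$lat, rep(37.5, 10))
  expect_false("gps" %in% prm$source)
})

test_that("the profile-likelihood Box-Cox exponent matches the MASS::boxcox grid maximum", {
  skip_if_not_installed("MASS")
  set.seed(3)
  y <- rlnorm(500, 2, 0.6)
  base <- as.POSIXct("2021-07-01 00:00:00", tz = "")
  rec <- data.table::data.table(
    record_id = seq_along(y), participant_id = "P001", source = "light",
    timestamp = base + seq_along(y) * 60, field = "lux", value = y,
    tag = NA_character_, lat = NA_real_, lon = NA_real_)
  lam <- transform_boxcox(rec)$params$lambda
  bc <- MASS::boxcox(yv ~ 1, data = data.frame(yv = y),
                     lambda = seq(-2, 2, 0.005), plotit = FALSE)
  expect_lt(abs(lam - bc$x[which.max(bc$y)]), 0.01)
})

test_that("daily features follow the category conventions (counts, mean, population variance)", {
  base <- as.POSIXct("2021-07-05 09:00:00", tz = "")
  demo <- data.table::data.table(participant_id = "P001", gender = "female",
                                 age = 30)
  rec <- data.table::data.table(
    record_id = 1:5, participant_id = "P001",
    source = c("pedometer", "pedometer", "pedometer",
               "physical_activity", "physical_activity"),
    timestamp = base + (0:4) * 3600,
    field = c("steps", "steps", "steps", "duration_s", "duration_s"),
    value = c(100, 200, 50, 600, 1200),
    tag = c(NA, NA, NA, "walking", "running"),
    lat = NA_real_, lon = NA_real_)
  mat <- extract_daily_features(rec, demo, "ios")
  expect_equal(nrow(mat), 1L)
  expect_equal(mat$steps_n, 350)                       # cumulative count
  expect_equal(mat$activity_active_duration_mean, 900) # mean of 600, 1200
  expect_equal(mat$activity_active_duration_var, 9e4)  # population variance
  expect_equal(mat$age_group, "<=30")                  # age 30 boundary
  expect_equal(mat$gender, "female")
  expect_true(is.na(mat$loc_time_home_h))              # no GPS that day
})

test_that("location features handle stationary days, known distances and split days", {
  # stationary day: all 96 fixes at the home centroid -> 24 h at home,
  # zero travel, one place
  home <- gps_day(lat = rep(37.5, 96), lon = rep(127.0, 96))
  labelled <- clean_gps(home)$kept
  f <- extract_location_features(labelled)
  expect_equal(f$loc_time_home_h, 24)
  expect_equal(f$loc_total_distance_km, 0)
  expect_equal(f$loc_visited_places_n, 1)
  expect_equal(f$loc_displacement_sd_km, 0)
  # two points 0.009 degrees apart in latitude: about 1.0 km apart
  expect_equal(greatcircle_km(37.5, 127, 37.509, 127), 1.0, tolerance = 0.01)
  two <- gps_day(lat = c(rep(37.5, 12), rep(37.509, 12)),
                 lon = rep(127.0, 24), every_min = 60)
  lab2 <- clean_gps(two, interval_min = 60, min_stay_h = 4)$kept
  f2 <- extract_location_features(lab2)
  expect_equal(f2$loc_total_distance_km, 1.0, tolerance = 0.01)
  expect_equal(f2$loc_max_home_distance_km, 1.0, tolerance = 0.01)
  expect_equal(f2$loc_visited_places_n, 2)
  # 48/48 home/work split: 12 h each by the dwell apportionment
  split <- gps_day(lat = c(rep(37.5, 48), rep(37.6, 48)),
                   lon = rep(127.0, 96))
  lab3 <- clean_gps(split)$kept
  f3 <- extract_location_features(lab3)
  hw <- sort(c(f3$loc_time_home_h, f3$loc_time_work_h))
  expect_equal(hw, c(12, 12))
})

test_that("pruning drops quasi-constant and poorly observed columns but nothing else", {
  set.seed(11)
  mat <- data.table::data.table(
    participant_id = rep("P001", 100),
    date = as.Date("2021-07-01") + 0:99,
    gender = "female", age_group = "<=30",
    day_of_week = rep_len(1:7, 100),
    constant = 5,
    nearly_constant = c(rep(0, 97), 1, 2, 3),
    holey = c(rnorm(75), rep(NA, 25)),
    healthy = rnorm(100))
  out <- prune_features(mat)
  expect_equal(attr(out, "dropped_variance"),
               c("constant", "nearly_constant"))
  expect_equal(attr(out, "dropped_missing"), "holey")   # 25% > 20%
  expect_true(all(c("healthy", "gender", "age_group", "day_of_week")
                  %in% names(out)))
  # fully observed, full-variance matrix: identity
  ok <- mat[, c("participant_id", "date", "healthy"), with = FALSE]
  expect_equal(names(prune_features(ok)), names(ok))
})

test_that("the assembled pre-pruning schema has 68 Android and 34 iOS columns", {
  expect_equal(nrow(feature_schema("android")), 68L)
  expect_equal(nrow(feature_schema("ios")), 34L)
  expect_false(anyDuplicated(feature_schema("android")$column) > 0)
  expect_false(anyDuplicated(feature_schema("ios")$column) > 0)
  expect_true(all(feature_schema("ios")$column %in%
                    feature_schema("android")$column))
})
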