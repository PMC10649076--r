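# EMA pipeline: reliability/speeder filters, daily aggregation, per-item
# interpolation, severity classification, symptom binarisation.

test_that("reliability filter voids responses with trap discrepancy strictly above one point", {
  resp <- rbind(
    make_responses(1, item2 = 2L, trap = 0L),   # discrepancy 2 -> discarded
    make_responses(1, item2 = 1L, trap = 2L),   # discrepancy 1 -> kept
    make_responses(1, item2 = 3L, trap = 3L),   # discrepancy 0 -> kept
    make_responses(1, item2 = 0L, trap = 3L)    # discrepancy 3 -> discarded
  )
  resp$response_id <- sprintf("R%04d", seq_len(nrow(resp)))
  out <- filter_reliability(resp)
  expect_equal(nrow(out$discarded), 2L)
  expect_equal(out$discarded$item2, c(2L, 0L))
  expect_equal(nrow(out$kept) + nrow(out$discarded), nrow(resp))
  expect_length(intersect(out$kept$response_id, out$discarded$response_id), 0)
})

test_that("Speeder Index is 1 at or above the pooled median and the duration ratio below", {
  resp <- make_responses(5, duration = c(30, 60, 90, 120, 150))
  si <- compute_speeder_index(resp)$si
  expect_equal(si[3:5], rep(1, 3))          # median 90: at/above -> 1
  expect_equal(si[1:2], c(30, 60) / 90)
  # inserting a fast response changes the median; oracle recomputes both
  resp2 <- make_responses(6, duration = c(30, 45, 60, 90, 120, 150))
  med <- median(resp2$duration_s)
  si2 <- compute_speeder_index(resp2)$si
  expect_equal(si2[2], 45 / med)
  # all equal durations: every response sits at the median
  expect_equal(compute_speeder_index(make_responses(4, duration = 60))$si,
               rep(1, 4))
  expect_error(compute_speeder_index(make_responses(0)), "no responses")
})

test_that("speeder filter voids the lowest decile of Speeder Index values", {
  resp <- make_responses(100, duration = seq(10, 505, by = 5))
  idx <- compute_speeder_index(resp)
  out <- filter_speeders(idx, 0.10)
  expect_equal(nrow(out$discarded), 10L)     # distinct si values: exact decile
  expect_equal(sort(out$discarded$duration_s), seq(10, 55, by = 5))
  expect_equal(nrow(filter_speeders(idx, 0)$discarded), 0L)
  const <- compute_speeder_index(make_responses(20, duration = 60))
  expect_equal(nrow(filter_speeders(const, 0.10)$discarded), 0L)
})

test_that("daily aggregation averages per item within a participant-day", {
  resp <- make_responses(2, item2 = c(1L, 2L))
  resp$timestamp <- as.POSIXct(c("2021-07-01 10:00", "2021-07-01 18:00"),
                               tz = "")
  daily <- aggregate_daily(resp)
  expect_equal(nrow(daily), 1L)
  expect_equal(daily$item2, 1.5)
  expect_false(daily$interpolated)
  # single response: record equals the response; absent day: no record
  one <- aggregate_daily(make_responses(1, item2 = 3L))
  expect_equal(one$item2, 3)
  expect_equal(one$date, as.Date("2021-07-01"))
})

test_that("interpolation is linear per item, sums to the total, and never extrapolates", {
  # item observed day1 = 1, day4 = 4 (on the 0-3 scale use 0..3): use item2
  obs <- make_daily(matrix(0, 2, 9))
  obs$date <- as.Date(c("2021-07-01", "2021-07-04"))
  obs$item2 <- c(0, 3)
  obs$total <- c(0, 3)
  dense <- interpolate_daily_items(obs)
  expect_equal(nrow(dense), 4L)
  expect_equal(dense$item2, c(0, 1, 2, 3))
  expect_equal(dense$interpolated, c(FALSE, TRUE, TRUE, FALSE))
  # interpolated total equals the sum of interpolated items
  obs2 <- make_daily(rbind(rep(0, 9), c(3, rep(0, 8))))
  obs2$date <- as.Date(c("2021-07-01", "2021-07-03"))
  dense2 <- interpolate_daily_items(obs2)
  mid <- dense2[dense2$date == as.Date("2021-07-02")]
  expect_equal(mid$item1, 1.5)
  expect_equal(mid$total, 1.5, tolerance = 1e-12)
  expect_equal(mid$total, sum(as.matrix(mid[, paste0("item", 1:9),
                                            with = FALSE])))
  # dense input: identity (idempotence)
  again <- interpolate_daily_items(dense2)
  expect_equal(again$item1, dense2$item1)
  expect_equal(nrow(again), nrow(dense2))
  # < 2 observed days: participant dropped with a warning
  expect_warning(out <- interpolate_daily_items(make_daily(matrix(1, 1, 9))),
                 "excluding")
  expect_equal(nrow(out), 0L)
})

test_that("interpolation reproduces already-linear per-item series exactly", {
  days <- 10
  items <- sapply(1:9, function(j) seq(0, 3, length.out = days) * (j %% 2))
  obs <- make_daily(items)
  keep <- c(1, 4, 7, 10)       # knock out interior days; ends kept
  dense <- interpolate_daily_items(obs[keep])
  expect_equal(as.matrix(dense[, paste0("item", 1:9), with = FALSE]),
               unname(items), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("severity cutoffs are half-open at 10 and 20 and exhaustive over integer totals", {
  expect_equal(as.character(classify_severity(9.9)), "none_mild")
  expect_equal(as.character(classify_severity(10)), "moderate")
  expect_equal(as.character(classify_severity(19.99)), "moderate")
  expect_equal(as.character(classify_severity(20)), "severe")
  cls <- classify_severity(0:27)
  expect_false(anyNA(cls))
  expect_equal(unname(table(cls)), c(10L, 10L, 8L), ignore_attr = TRUE)
  expect_error(classify_severity(-0.1), "0, 27")
  expect_error(classify_severity(27.5), "0, 27")
})

test_that("symptom presence is strictly greater-than-zero, including fractional scores", {
  expect_false(binarize_symptoms(0))
  expect_true(binarize_symptoms(0.5))
  expect_true(binarize_symptoms(3))
  expect_error(binarize_symptoms(3.2), "0, 3")
})

test_that("the EMA pipeline keeps filter partitions disjoint and records internally consistent", {
  cfg <- simulation_config(n_participants = 4, n_days = 45, seed = 3,
                           speeder_fraction = 0.08,
                           trap_error_fraction = 0.05)
  bundle <- simulate_cohort(cfg)
  out <- process_ema(bundle$ema)
  cnt <- out$counts
  expect_equal(cnt$input,
               cnt$reliability_discarded + cnt$speeder_discarded + cnt$kept)
  daily <- out$daily
  items <- as.matrix(daily[, paste0("item", 1:9), with = FALSE])
  expect_equal(daily$total, rowSums(items), tolerance = 1e-9)
  expect_equal(as.character(daily$severity),
               as.character(classify_severity(daily$total)))
  pres <- as.matrix(daily[, paste0("present", 1:9), with = FALSE])
  expect_identical(unname(pres), unname(items > 0))
})
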