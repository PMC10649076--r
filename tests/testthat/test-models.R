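# Symptom models: imbalance screening, SMOTE, LOSO evaluation, probability
# model training and prediction.

test_that("the imbalance screen excludes symptoms strictly beyond the 4:1 boundary", {
  mk <- function(n1, n0) {
    lab <- data.table::data.table(x = 1)
    for (j in 1:9) data.table::set(lab, j = paste0("present", j),
                                   value = TRUE)
    lab <- lab[rep(1L, n1 + n0)]
    for (j in 1:9) data.table::set(lab, j = paste0("present", j),
                                   value = rep(c(TRUE, FALSE), c(n1, n0)))
    lab
  }
  expect_true(assess_symptom_balance(mk(100, 26))$included[1])   # 3.85 < 4
  expect_true(assess_symptom_balance(mk(100, 25))$included[1])   # exactly 4
  expect_false(assess_symptom_balance(mk(100, 24))$included[1])  # 4.17 > 4
  expect_true(assess_symptom_balance(mk(50, 50))$included[1])
  expect_false(assess_symptom_balance(mk(24, 100))$included[1])  # below 1/4
  expect_false(assess_symptom_balance(mk(100, 0))$included[1])   # one class
})

test_that("SMOTE balances classes with convex minority combinations, deterministically", {
  set.seed(4)
  x <- matrix(rnorm(125 * 3), 125, 3)
  y <- rep(c(TRUE, FALSE), c(100, 25))
  out <- oversample_minority(x, y, seed = 99)
  expect_equal(sum(out$y), sum(!out$y))
  expect_equal(out$n_synthetic, 75L)
  syn <- out$x[126:200, , drop = FALSE]
  # synthetic rows lie inside the minority bounding box (convex combinations)
  xm <- x[!y, , drop = FALSE]
  for (j in 1:3) {
    expect_true(all(syn[, j] >= min(xm[, j]) - 1e-12))
    expect_true(all(syn[, j] <= max(xm[, j]) + 1e-12))
  }
  # determinism under the seed
  out2 <- oversample_minority(x, y, seed = 99)
  expect_identical(out$x, out2$x)
  # already balanced: identity
  xb <- x[1:50, ]
  yb <- rep(c(TRUE, FALSE), 25)
  outb <- oversample_minority(xb, yb, seed = 1)
  expect_identical(outb$x, xb)
  expect_equal(outb$n_synthetic, 0L)
  # tiny minority: k reduced with a warning
  ys <- rep(c(TRUE, FALSE), c(122, 3))
  expect_warning(outs <- oversample_minority(x, ys, k = 5, seed = 1),
                 "using k = 2")
  expect_equal(sum(!outs$y), sum(outs$y))
})

test_that("LOSO symptom folds never leak the held-out participant and pool metrics correctly", {
  w <- make_symptom_world()
  cv <- loso_symptom_cv(w$features, w$daily, symptoms = c(1, 2), seed = 31)
  expect_length(cv$folds, 6L)
  for (f in cv$folds) {
    expect_false(f$test_participant %in% f$train_participants)
  }
  # every participant-day predicted exactly once per symptom
  expect_equal(nrow(cv$predictions), 2L * nrow(w$features))
  # metrics equal a brute-force recomputation from the pooled predictions
  for (j in c(1, 2)) {
    sub <- cv$predictions[cv$predictions$symptom == j]
    tp <- sum(sub$truth & sub$pred)
    fp <- sum(!sub$truth & sub$pred)
    fn <- sum(sub$truth & !sub$pred)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    m <- cv$metrics[cv$metrics$symptom == j]
    expect_equal(m$precision, prec, tolerance = 1e-12)
    expect_equal(m$recall, rec, tolerance = 1e-12)
    expect_equal(m$f1, f1, tolerance = 1e-12)
  }
  # the learnable symptom clearly beats the coin flip
  expect_gt(cv$metrics$f1[cv$metrics$symptom == 1],
            cv$metrics$f1[cv$metrics$symptom == 2])
})

test_that("confusion counts TP=8 FP=2 FN=2 give precision, recall and F1 of 0.8", {
  truth <- rep(c(TRUE, TRUE, FALSE, FALSE), c(8, 2, 2, 40))
  pred <- rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 2, 2, 40))
  m <- symprof:::binary_prf(truth, pred)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
})

test_that("probability models emit [0,1] outputs, constant fallbacks, and schema errors", {
  w <- make_symptom_world()
  # force symptom 9 single-class to trigger the fallback
  data.table::set(w$daily, j = "present9", value = TRUE)
  expect_length(
    capture.output(ms <- train_symptom_models(w$features, w$daily, seed = 3),
                   type = "message"), 0)
  expect_s3_class(ms, "symptom_model_set")
  expect_true(ms$fallback[9])
  expect_false(any(ms$fallback[1:8]))
  sh <- predict_symptom_probabilities(ms, w$features)
  probs <- as.matrix(sh[, paste0("p", 1:9), with = FALSE])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_true(all(probs[, 9] == 1))           # constant fallback emits 1.0
  # duplicated input rows give identical outputs
  dup <- rbind(w$features[1], w$features[1])
  sh_dup <- predict_symptom_probabilities(ms, dup)
  expect_equal(as.numeric(sh_dup[1, paste0("p", 1:9), with = FALSE]),
               as.numeric(sh_dup[2, paste0("p", 1:9), with = FALSE]))
  # schema violations name the missing columns
  broken <- data.table::copy(w$features)[, "signal" := NULL]
  expect_error(predict_symptom_probabilities(ms, broken), "signal")
})

test_that("per-symptom F1 tracks planted signal strength across seeds", {
  # nine symptoms with linearly decreasing feature-label signal; pooled
  # LOSO F1 should follow the planted order (rank correlation over 5 seeds)
  strengths <- seq(2, 0, length.out = 9)
  rhos <- vapply(1:5, function(s) {
    set.seed(800 + s)
    keys <- data.table::CJ(participant_id = sprintf("P%03d", 1:10),
                           date = as.Date("2021-07-01") + 0:39)
    n <- nrow(keys)
    feat <- data.table::copy(keys)
    for (k in 1:4) data.table::set(feat, j = paste0("f", k),
                                   value = rnorm(n))
    daily <- data.table::copy(keys)
    for (j in 1:9) {
      score <- strengths[j] * feat$f1 + rnorm(n)
      data.table::set(daily, j = paste0("present", j),
                      value = score > median(score))
    }
    cv <- loso_symptom_cv(feat, daily, symptoms = 1:9, seed = 900 + s)
    cor(cv$metrics$f1, strengths[cv$metrics$symptom], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.5)
})
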