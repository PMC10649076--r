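# Three-class depression-severity prediction on the months after the
# profiling window, comparing raw sensor features against symptom-profile
# vectors as model input, under leave-one-subject-out cross-validation with
# weighted multi-class metrics.

fit_predict_severity <- function(model, x_train, y_train, x_test, seed,
                                 feature_weights = NULL) {
  lev <- levels(y_train)
  if (!is.null(feature_weights) && length(feature_weights) != ncol(x_train)) {
    stop_config("feature_weights must have one entry per feature column")
  }
  if (model == "xgb") {
    d <- xgboost::xgb.DMatrix(x_train, label = as.integer(y_train) - 1L,
                              nthread = 1)
    params <- list(objective = "multi:softmax", num_class = length(lev),
                   nthread = 1, seed = seed)
    if (!is.null(feature_weights)) {
      # per-feature sampling weights; only effective with column subsampling
      xgboost::setinfo(d, "feature_weights", feature_weights)
      params$colsample_bynode <- 0.8
    }
    fit <- xgboost::xgb.train(params = params, data = d, nrounds = XGB_NROUNDS,
                              verbose = 0)
    idx <- predict(fit, xgboost::xgb.DMatrix(x_test, nthread = 1))
    lev[idx + 1L]
  } else if (model == "rf") {
    args <- list(y = y_train, x = as.data.frame(x_train), num.trees = 300L,
                 seed = seed, num.threads = 1L)
    if (!is.null(feature_weights)) {
      args$split.select.weights <- feature_weights / max(feature_weights)
    }
    fit <- do.call(ranger::ranger, args)
    as.character(predict(fit, as.data.frame(x_test),
                         num.threads = 1L)$predictions)
  } else if (model == "svm") {
    # margin-based model: weighting means scaling the input columns
    if (!is.null(feature_weights)) {
      x_train <- sweep(x_train, 2L, feature_weights, "*")
      x_test <- sweep(x_test, 2L, feature_weights, "*")
    }
    const <- apply(x_train, 2L, function(v) length(unique(v)) < 2L)
    fit <- with_seed(seed, e1071::svm(x_train[, !const, drop = FALSE],
                                      y_train, scale = TRUE))
    as.character(predict(fit, x_test[, !const, drop = FALSE]))
  } else if (model == "multinom") {
    if (!is.null(feature_weights)) {
      x_train <- sweep(x_train, 2L, feature_weights, "*")
      x_test <- sweep(x_test, 2L, feature_weights, "*")
    }
    df_tr <- as.data.frame(x_train)
    names(df_tr) <- make.names(names(df_tr))
    df_te <- as.data.frame(x_test)
    names(df_te) <- make.names(names(df_te))
    df_tr$.y <- y_train
    fit <- with_seed(seed, nnet::multinom(.y ~ ., data = df_tr,
                                          decay = 1e-4, maxit = 200,
                                          trace = FALSE, MaxNWts = 5000))
    as.character(predict(fit, df_te))
  } else {
    stop_config("unknown model '%s'; supported models: %s", model,
                paste(SEVERITY_MODELS, collapse = ", "))
  }
}

#' Weighted multi-class classification metrics
#'
#' Computes one-vs-rest precision, recall and F1 separately for each class
#' and averages them weighted by class support, so dominant classes do not
#' mask minority-class performance any more than their prevalence warrants.
#'
#' @param y_true,y_pred factors or characters over the severity classes.
#' @param levels class labels defining the averaging order.
#' @return list with `weighted` (f1/precision/recall) and `per_class`
#'   (data.table with per-class metrics and supports).
#' @export
weighted_classification_metrics <- function(y_true, y_pred,
                                            levels = SEVERITY_LEVELS) {
  if (length(y_true) == 0L) {
    stop_config("weighted_classification_metrics: empty input")
  }
  if (length(y_true) != length(y_pred)) {
    stop_config("weighted_classification_metrics: length mismatch")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  per <- lapply(levels, function(cl) {
    m <- binary_prf(y_true == cl, y_pred == cl)
    list(class = cl, support = sum(y_true == cl), f1 = m$f1,
         precision = m$precision, recall = m$recall)
  })
  per <- data.table::rbindlist(per)
  w <- per$support / sum(per$support)
  list(
    weighted = list(f1 = sum(w * per$f1), precision = sum(w * per$precision),
                    recall = sum(w * per$recall)),
    per_class = per
  )
}

#' Assemble a severity dataset from an input representation
#'
#' Joins an input table (either a daily feature matrix or a symptom-profile
#' table with `sp1..sp9`) with daily severity labels on (participant, day).
#'
#' @param input feature matrix or SP table with `participant_id`, `date`.
#' @param daily daily records carrying a `severity` column.
#' @return list with `x` (numeric matrix), `y` (factor), `keys` and
#'   `participants`.
#' @export
severity_dataset <- function(input, daily) {
  input <- as_dt(input, "input representation")
  daily <- as_dt(daily, "daily records")
  check_columns(daily, c("participant_id", "date", "severity"),
                "daily records")
  merged <- daily[, c("participant_id", "date", "severity"),
                  with = FALSE][input, on = c("participant_id", "date"),
                                nomatch = NULL]
  enc <- encode_feature_matrix(
    merged[, setdiff(names(merged), "severity"), with = FALSE])
  list(x = enc$x,
       y = factor(as.character(merged$severity), levels = SEVERITY_LEVELS),
       keys = enc$keys,
       participants = enc$keys$participant_id)
}

#' Leave-one-subject-out severity classification
#'
#' One fold per participant; the held-out participant's days are predicted
#' by a model trained on all other participants. Missing feature cells are
#' filled with training-fold medians inside each fold. Predictions are
#' pooled and summarised with weighted metrics.
#'
#' @param dataset a list from [severity_dataset()] (fields `x`, `y`,
#'   `participants`, `keys`).
#' @param model one of `"xgb"`, `"rf"`, `"svm"`, `"multinom"`.
#' @param seed integer seed.
#' @param feature_weights optional per-feature weights (weighted
#'   symptom-profile mode); applied as feature-sampling weights for the
#'   tree models and as input scaling for the margin/linear models.
#' @return object of class `severity_report`.
#' @export
run_loso_severity <- function(dataset, model = "xgb", seed = 1L,
                              feature_weights = NULL) {
  if (!model %in% SEVERITY_MODELS) {
    stop_config("unknown model '%s'; supported models: %s", model,
                paste(SEVERITY_MODELS, collapse = ", "))
  }
  participants <- unique(dataset$participants)
  if (length(participants) < 2L) {
    stop_config("run_loso_severity: need at least 2 participants")
  }
  preds <- character(length(dataset$y))
  folds <- list()
  for (fi in seq_along(participants)) {
    p <- participants[fi]
    te <- which(dataset$participants == p)
    tr <- which(dataset$participants != p)
    folds[[fi]] <- list(test_participant = p,
                        train_participants = setdiff(participants, p))
    imp <- median_impute(dataset$x[tr, , drop = FALSE],
                         dataset$x[te, , drop = FALSE])
    y_tr <- droplevels(dataset$y[tr])
    preds[te] <- fit_predict_severity(model, imp$train, y_tr, imp$test,
                                      seed = seed,
                                      feature_weights = feature_weights)
  }
  metrics <- weighted_classification_metrics(dataset$y, preds)
  structure(list(
    model = model,
    weighted = metrics$weighted,
    per_class = metrics$per_class,
    predictions = data.table(dataset$keys, truth = as.character(dataset$y),
                             pred = preds),
    folds = folds,
    seed = seed,
    n = length(preds),
    weighted_input = !is.null(feature_weights)
  ), class = "severity_report")
}

#' @export
print.severity_report <- function(x, ...) {
  cat(sprintf("LOSO severity classification (%s%s): %d participant folds, %d days\n",
              x$model, if (x$weighted_input) ", weighted input" else "",
              length(x$folds), x$n))
  cat(sprintf("  weighted F1 %.3f, precision %.3f, recall %.3f\n",
              x$weighted$f1, x$weighted$precision, x$weighted$recall))
  invisible(x)
}

#' Majority-class baseline weighted metrics
#'
#' Weighted metrics of the constant classifier that predicts the most
#' frequent severity class; the reference point against which any model has
#' to earn its keep.
#'
#' @param y factor or character vector of severity labels.
#' @return list with `weighted` metrics, `per_class` and `majority` class.
#' @export
majority_class_baseline <- function(y) {
  y <- as.character(y)
  maj <- names(which.max(table(y)))
  m <- weighted_classification_metrics(y, rep(maj, length(y)))
  c(m, list(majority = maj))
}

#' Compare sensor-feature and symptom-profile input representations
#'
#' Runs LOSO severity classification with both input representations for
#' each model family and reports the metric deltas (symptom profile minus
#' sensor features). Both datasets must cover the identical participant-day
#' universe.
#'
#' @param sensor_dataset,sp_dataset lists from [severity_dataset()].
#' @param models model families to compare.
#' @param seed integer seed.
#' @param sp_feature_weights optional per-feature weights applied to the
#'   symptom-profile input (weighted SP mode).
#' @return object of class `sp_comparison`: per-model metric table plus
#'   averages and the underlying reports.
#' @export
compare_input_representations <- function(sensor_dataset, sp_dataset,
                                          models = SEVERITY_MODELS,
                                          seed = 1L,
                                          sp_feature_weights = NULL) {
  k1 <- sensor_dataset$keys
  k2 <- sp_dataset$keys
  if (nrow(k1) != nrow(k2) ||
      !all(k1$participant_id == k2$participant_id & k1$date == k2$date)) {
    stop_config("compare_input_representations: datasets cover different participant-day rows")
  }
  if (!identical(as.character(sensor_dataset$y), as.character(sp_dataset$y))) {
    stop_config("compare_input_representations: datasets carry different labels")
  }
  rows <- list()
  reports <- list()
  for (m in models) {
    r_sensor <- run_loso_severity(sensor_dataset, m, seed = seed)
    r_sp <- run_loso_severity(sp_dataset, m, seed = seed,
                              feature_weights = sp_feature_weights)
    reports[[m]] <- list(sensor = r_sensor, sp = r_sp)
    rows[[m]] <- list(
      model = m,
      f1_sensor = r_sensor$weighted$f1, f1_sp = r_sp$weighted$f1,
      delta_f1 = r_sp$weighted$f1 - r_sensor$weighted$f1,
      precision_sensor = r_sensor$weighted$precision,
      precision_sp = r_sp$weighted$precision,
      delta_precision = r_sp$weighted$precision - r_sensor$weighted$precision,
      recall_sensor = r_sensor$weighted$recall,
      recall_sp = r_sp$weighted$recall,
      delta_recall = r_sp$weighted$recall - r_sensor$weighted$recall)
  }
  tab <- data.table::rbindlist(rows)
  structure(list(
    table = tab,
    averages = list(delta_f1 = mean(tab$delta_f1),
                    delta_precision = mean(tab$delta_precision),
                    delta_recall = mean(tab$delta_recall)),
    reports = reports,
    seed = seed
  ), class = "sp_comparison")
}

#' @export
print.sp_comparison <- function(x, ...) {
  cat("Severity prediction: sensor features vs symptom profiles (LOSO)\n")
  print(x$table[, c("model", "f1_sensor", "f1_sp", "delta_f1"), with = FALSE],
        digits = 3)
  cat(sprintf("  average deltas: F1 %+0.3f, precision %+0.3f, recall %+0.3f\n",
              x$averages$delta_f1, x$averages$delta_precision,
              x$averages$delta_recall))
  invisible(x)
}

#' Group-averaged symptom profiles vs rescaled self-report scores
#'
#' For each severity group, averages the symptom-profile elements over the
#' group's participant-days and compares them with the group means of the
#' original item scores rescaled to [0, 1] (score / 3).
#'
#' @param sp symptom-profile table (`participant_id`, `date`, `sp1..sp9`).
#' @param daily daily records with `severity` and item scores.
#' @return data.table with one row per (group, symptom): `mean_sp`,
#'   `mean_rescaled_ema` and their discrepancy.
#' @export
summarize_group_profiles <- function(sp, daily) {
  sp <- as_dt(sp, "symptom profile")
  daily <- as_dt(daily, "daily records")
  check_columns(sp, c("participant_id", "date", sp_cols()), "symptom profile")
  check_columns(daily, c("participant_id", "date", "severity", item_cols()),
                "daily records")
  merged <- daily[, c("participant_id", "date", "severity", item_cols()),
                  with = FALSE][sp, on = c("participant_id", "date"),
                                nomatch = NULL]
  empty <- setdiff(SEVERITY_LEVELS, unique(as.character(merged$severity)))
  if (length(empty) > 0L) {
    warning(sprintf("summarize_group_profiles: no rows for group(s): %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  rows <- list()
  for (g in intersect(SEVERITY_LEVELS, unique(as.character(merged$severity)))) {
    sub <- merged[as.character(merged$severity) == g]
    for (j in 1:9) {
      mean_sp <- mean(sub[[paste0("sp", j)]])
      mean_ema <- mean(sub[[paste0("item", j)]]) / 3
      rows[[length(rows) + 1L]] <- list(
        group = g, symptom = j, name = PHQ9_ITEMS[j], mean_sp = mean_sp,
        mean_rescaled_ema = mean_ema, discrepancy = mean_ema - mean_sp,
        n_days = nrow(sub))
    }
  }
  data.table::rbindlist(rows)
}
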