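# Per-symptom binary classification: class-balance screening, SMOTE
# oversampling, leave-one-subject-out evaluation, and the nine
# gradient-boosted probability models whose outputs form the symptom
# heterogeneity (SH) vectors.

#' Screen symptoms for severe class imbalance
#'
#' A symptom is excluded from the classification evaluation when one class
#' holds more than 4 times (or less than 1/4 of) the samples of the other;
#' a ratio of exactly 4 (or 1/4) is still included.
#'
#' @param labels table with `present1..present9` logical columns.
#' @return data.table with one row per symptom: counts, present/absent
#'   ratio and the `included` flag.
#' @export
assess_symptom_balance <- function(labels) {
  labels <- as_dt(labels, "labels")
  check_columns(labels, presence_cols(), "labels")
  res <- lapply(1:9, function(j) {
    y <- labels[[paste0("present", j)]]
    n1 <- sum(y)
    n0 <- sum(!y)
    ratio <- n1 / n0
    list(symptom = j, name = PHQ9_ITEMS[j], n_present = n1, n_absent = n0,
         ratio = ratio,
         included = is.finite(ratio) && ratio <= 4 && ratio >= 0.25)
  })
  data.table::rbindlist(res)
}

# median imputation fitted on training rows and applied to both sets;
# all-missing columns fall back to zero
median_impute <- function(x_train, x_test = NULL) {
  med <- apply(x_train, 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(x) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- med[j]
    }
    x
  }
  list(train = fill(x_train), test = if (is.null(x_test)) NULL else
    fill(x_test), medians = med)
}

#' SMOTE: synthetic minority oversampling to class parity
#'
#' Synthesises minority-class rows as convex combinations of a minority row
#' and one of its k nearest minority neighbours until both classes hold the
#' same number of rows. Applied to training folds only; deterministic under
#' the seed.
#'
#' @param x numeric feature matrix (no missing values).
#' @param y logical (or two-level) class vector.
#' @param k number of nearest neighbours (reduced with a warning when the
#'   minority class is smaller than k + 1).
#' @param seed integer seed.
#' @return list with the augmented `x`, `y` and `n_synthetic`.
#' @export
oversample_minority <- function(x, y, k = 5L, seed = 1L) {
  if (anyNA(x)) stop_config("oversample_minority: x must not contain missing values")
  y <- as.logical(y)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == n0) return(list(x = x, y = y, n_synthetic = 0L))
  minority <- if (n1 < n0) which(y) else which(!y)
  n_syn <- abs(n1 - n0)
  xm <- x[minority, , drop = FALSE]
  nm <- nrow(xm)
  syn <- with_seed(seed, {
    if (nm == 1L) {
      xm[rep(1L, n_syn), , drop = FALSE]
    } else {
      k_use <- min(k, nm - 1L)
      if (k_use < k) {
        warning(sprintf("oversample_minority: minority class has %d rows; using k = %d",
                        nm, k_use), call. = FALSE)
      }
      d <- as.matrix(dist(xm))
      diag(d) <- Inf
      nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_use)]))
      base <- sample.int(nm, n_syn, replace = TRUE)
      nbr <- nn[cbind(base, sample.int(k_use, n_syn, replace = TRUE))]
      gap <- runif(n_syn)
      xm[base, , drop = FALSE] +
        gap * (xm[nbr, , drop = FALSE] - xm[base, , drop = FALSE])
    }
  })
  minority_is_present <- n1 < n0
  list(x = rbind(x, syn),
       y = c(y, rep(minority_is_present, n_syn)),
       n_synthetic = n_syn)
}

fit_binary_xgb <- function(x, y, seed, nrounds = XGB_NROUNDS) {
  d <- xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1, seed = seed),
    data = d, nrounds = nrounds, verbose = 0)
}

binary_prf <- function(truth, pred) {
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

# join an encoded feature matrix with daily presence labels on
# (participant_id, date)
join_features_labels <- function(features, daily) {
  features <- as_dt(features, "feature matrix")
  daily <- as_dt(daily, "daily records")
  check_columns(daily, c("participant_id", "date", presence_cols()),
                "daily records")
  merged <- daily[, c("participant_id", "date", presence_cols()),
                  with = FALSE][features, on = c("participant_id", "date"),
                                nomatch = NULL]
  enc <- encode_feature_matrix(
    merged[, setdiff(names(merged), presence_cols()), with = FALSE])
  list(keys = enc$keys, x = enc$x,
       labels = as.matrix(merged[, presence_cols(), with = FALSE]))
}

#' Leave-one-subject-out evaluation of per-symptom classifiers
#'
#' One fold per participant: the held-out participant's days are predicted
#' by a gradient-boosted model trained on everyone else, with SMOTE applied
#' inside the training fold only. Metrics are pooled over all held-out
#' predictions.
#'
#' @param features pruned daily feature matrix (with `participant_id`,
#'   `date`).
#' @param daily daily symptom records carrying `present1..present9`.
#' @param symptoms symptom indices to evaluate; default: those passing the
#'   imbalance screen of [assess_symptom_balance()].
#' @param seed integer seed.
#' @return list with `metrics` (per symptom), `predictions`, `folds`
#'   (train/test participant sets per fold) and `balance`.
#' @export
loso_symptom_cv <- function(features, daily, symptoms = NULL, seed = 1L) {
  js <- join_features_labels(features, daily)
  balance <- assess_symptom_balance(
    data.table::as.data.table(js$labels))
  if (is.null(symptoms)) symptoms <- balance$symptom[balance$included]
  participants <- unique(js$keys$participant_id)
  if (length(participants) < 2L) {
    stop_config("loso_symptom_cv: need at least 2 participants")
  }
  preds <- list()
  folds <- list()
  for (fi in seq_along(participants)) {
    p <- participants[fi]
    test_idx <- which(js$keys$participant_id == p)
    train_idx <- which(js$keys$participant_id != p)
    folds[[fi]] <- list(test_participant = p,
                        train_participants = setdiff(participants, p))
    imp <- median_impute(js$x[train_idx, , drop = FALSE],
                         js$x[test_idx, , drop = FALSE])
    for (j in symptoms) {
      y_tr <- js$labels[train_idx, j]
      if (length(unique(y_tr)) < 2L) next
      sm <- oversample_minority(imp$train, y_tr, seed = seed + fi)
      fit <- fit_binary_xgb(sm$x, sm$y, seed = seed)
      prob <- predict(fit, xgboost::xgb.DMatrix(imp$test, nthread = 1))
      preds[[length(preds) + 1L]] <- data.table(
        participant_id = p, date = js$keys$date[test_idx], symptom = j,
        prob = prob, truth = js$labels[test_idx, j])
    }
  }
  if (length(preds) == 0L) {
    warning("loso_symptom_cv: no evaluable symptom (imbalance screen or single-class folds)",
            call. = FALSE)
    empty <- data.table(participant_id = character(0),
                        date = as.Date(character(0)), symptom = integer(0),
                        prob = numeric(0), truth = logical(0),
                        pred = logical(0))
    return(list(metrics = data.table(symptom = integer(0), f1 = numeric(0),
                                     precision = numeric(0),
                                     recall = numeric(0), n = integer(0),
                                     name = character(0)),
                predictions = empty, folds = folds, balance = balance,
                seed = seed))
  }
  predictions <- data.table::rbindlist(preds)
  predictions[, "pred" := predictions$prob >= 0.5]
  metrics <- predictions[, {
    m <- binary_prf(truth, pred)
    list(f1 = m$f1, precision = m$precision, recall = m$recall, n = .N)
  }, by = "symptom"]
  metrics[, "name" := PHQ9_ITEMS[metrics$symptom]]
  data.table::setorderv(metrics, "symptom")
  list(metrics = metrics[], predictions = predictions[], folds = folds,
       balance = balance, seed = seed)
}

#' Train the nine symptom probability models on first-month data
#'
#' Fits one gradient-boosted binary model per PHQ-9 symptom on the pooled
#' first-month participant-days. A symptom with a single class in the
#' training window gets a constant-probability fallback model and is
#' flagged.
#'
#' @param features pruned daily feature matrix restricted to the profiling
#'   month.
#' @param daily first-month daily records with presence labels.
#' @param seed integer seed.
#' @return object of class `symptom_model_set`.
#' @export
train_symptom_models <- function(features, daily, seed = 1L) {
  js <- join_features_labels(features, daily)
  models <- vector("list", 9L)
  fallback <- logical(9L)
  for (j in 1:9) {
    y <- js$labels[, j]
    if (length(unique(y)) < 2L) {
      fallback[j] <- TRUE
      models[[j]] <- list(type = "constant", p = as.numeric(y[1]))
    } else {
      models[[j]] <- fit_binary_xgb(js$x, y, seed = seed)
    }
  }
  structure(list(models = models, fallback = fallback,
                 schema = colnames(js$x), seed = seed,
                 n_train = nrow(js$x),
                 params = list(objective = "binary:logistic",
                               nrounds = XGB_NROUNDS)),
            class = "symptom_model_set")
}

#' @export
print.symptom_model_set <- function(x, ...) {
  cat(sprintf("Symptom probability models: 9 boosted models on %d features, %d training rows (seed %d)\n",
              length(x$schema), x$n_train, x$seed))
  if (any(x$fallback)) {
    cat("  constant-probability fallback for:",
        paste(PHQ9_ITEMS[x$fallback], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict daily symptom probabilities (SH vectors)
#'
#' @param model_set a `symptom_model_set`.
#' @param features daily feature matrix for the prediction window; must
#'   carry exactly the training schema.
#' @return data.table with `participant_id`, `date`, `p1..p9` in [0, 1].
#' @export
predict_symptom_probabilities <- function(model_set, features) {
  stopifnot(inherits(model_set, "symptom_model_set"))
  enc <- encode_feature_matrix(as_dt(features, "feature matrix"))
  missing <- setdiff(model_set$schema, colnames(enc$x))
  if (length(missing) > 0L) {
    stop_config("predict_symptom_probabilities: features are missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  x <- enc$x[, model_set$schema, drop = FALSE]
  out <- data.table::copy(enc$keys)
  for (j in 1:9) {
    m <- model_set$models[[j]]
    p <- if (is.list(m) && identical(m$type, "constant")) {
      rep(m$p, nrow(x))
    } else {
      predict(m, xgboost::xgb.DMatrix(x, nthread = 1))
    }
    data.table::set(out, j = paste0("p", j), value = p)
  }
  out[]
}
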