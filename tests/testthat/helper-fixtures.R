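# Shared fixtures and independent oracles for the test suite.

library(data.table)

# minimal EMA response table; items default to zero except where given
make_responses <- function(n, participant = "P001", item2 = 0L, trap = 0L,
                           duration = 60, start = "2021-07-01 10:00:00") {
  items <- matrix(0L, nrow = n, ncol = 9,
                  dimnames = list(NULL, paste0("item", 1:9)))
  items[, 2] <- rep_len(item2, n)
  dt <- data.table(
    response_id = sprintf("R%04d", seq_len(n)),
    participant_id = participant,
    timestamp = as.POSIXct(start, tz = "") + (seq_len(n) - 1L) * 86400
  )
  dt <- cbind(dt, as.data.table(items))
  dt[, trap := rep_len(as.integer(trap), n)]
  dt[, duration_s := rep_len(duration, n)]
  dt[]
}

# daily record table built directly from an item-score matrix (one row/day)
make_daily <- function(items, participant = "P001",
                       start = as.Date("2021-07-01"),
                       interpolated = FALSE) {
  items <- as.matrix(items)
  colnames(items) <- paste0("item", 1:9)
  dt <- data.table(participant_id = participant,
                   date = start + seq_len(nrow(items)) - 1L)
  dt <- cbind(dt, as.data.table(items))
  dt[, total := rowSums(items)]
  dt[, interpolated := rep_len(interpolated, nrow(items))]
  dt[, severity := classify_severity(total)]
  pres <- items > 0
  colnames(pres) <- paste0("present", 1:9)
  cbind(dt, as.data.table(pres))[]
}

# brute-force DBSCAN oracle: O(n^2) textbook implementation
dbscan_brute <- function(x, y, eps, min_pts) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0L) {
      q <- queue[1L]
      queue <- queue[-1L]
      for (m in nb[[q]]) {
        if (labels[m] == 0L) {
          labels[m] <- cl
          if (core[m]) queue <- c(queue, m)
        }
      }
    }
  }
  labels
}

# same-partition check up to label permutation (plus identical noise sets)
same_clustering <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- a > 0L
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# great-circle distance oracle (spherical law of cosines, R = 6371 km),
# independent of the haversine route used by the package
greatcircle_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(pmin(1, pmax(-1, d)))
}

# brute-force weighted multi-class metrics oracle
weighted_metrics_brute <- function(y_true, y_pred, levels) {
  f1s <- ps <- rs <- ns <- numeric(length(levels))
  for (i in seq_along(levels)) {
    cl <- levels[i]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[i] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    ps[i] <- p
    rs[i] <- r
    ns[i] <- sum(y_true == cl)
  }
  w <- ns / sum(ns)
  list(f1 = sum(w * f1s), precision = sum(w * ps), recall = sum(w * rs))
}

# sample skewness
skewness <- function(x) mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5

# a small feature/label world with a learnable feature -> symptom link
make_symptom_world <- function(n_participants = 6, n_days = 20, seed = 8) {
  set.seed(seed)
  keys <- data.table::CJ(participant_id = sprintf("P%03d", 1:n_participants),
                         date = as.Date("2021-07-01") + seq_len(n_days) - 1L)
  n <- nrow(keys)
  feat <- data.table::copy(keys)
  feat[, "signal" := rnorm(n)]
  feat[, "noise1" := rnorm(n)]
  feat[, "noise2" := rnorm(n)]
  daily <- data.table::copy(keys)
  pres <- matrix(FALSE, n, 9)
  pres[, 1] <- feat$signal + rnorm(n, 0, 0.4) > 0   # symptom 1 learnable
  pres[, 2] <- runif(n) < 0.5                       # symptom 2 coin flip
  for (j in 3:9) pres[, j] <- runif(n) < 0.3
  for (j in 1:9) data.table::set(daily, j = paste0("present", j),
                                 value = pres[, j])
  list(features = feat, daily = daily)
}
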