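# EMA (PHQ-9 self-report) processing: reliability and speeder filtering,
# daily aggregation, per-item linear interpolation, severity classification
# and symptom binarisation.
#
# Filter order is fixed: reliability -> speeder -> daily aggregation ->
# interpolation. Each filter partitions its input into disjoint kept and
# discarded sets.

#' Reliability (trap question) filter
#'
#' The trap question paraphrases PHQ-9 item 2 (depressed mood). A response is
#' discarded iff the absolute discrepancy between item 2 and the trap answer
#' is strictly greater than one point.
#'
#' @param responses EMA response table with columns `item2` and `trap`.
#' @return list with `kept` and `discarded` tables (exhaustive, disjoint).
#' @export
filter_reliability <- function(responses) {
  responses <- as_dt(responses, "responses")
  check_columns(responses, c("item2", "trap"), "EMA responses")
  bad <- abs(responses$item2 - responses$trap) > 1
  list(kept = responses[!bad], discarded = responses[bad])
}

#' Speeder Index of EMA responses
#'
#' The Speeder Index of a response is 1 if its duration is greater than or
#' equal to the median duration pooled over all responses of all
#' participants, and duration / median otherwise.
#'
#' @param responses EMA response table with a `duration_s` column.
#' @return The input with an `si` column appended.
#' @export
compute_speeder_index <- function(responses) {
  responses <- as_dt(responses, "responses")
  check_columns(responses, "duration_s", "EMA responses")
  if (nrow(responses) == 0L) {
    stop_config("compute_speeder_index: no responses supplied")
  }
  med <- median(responses$duration_s)
  out <- data.table::copy(responses)
  out[, "si" := pmin(1, out$duration_s / med)]
  out[]
}

#' Void the fastest responses by Speeder Index
#'
#' Discards responses whose Speeder Index falls strictly below the empirical
#' `fraction` quantile of the pooled Speeder Index distribution (default: the
#' lowest 10%).
#'
#' @param indexed output of [compute_speeder_index()].
#' @param fraction quantile cutoff in [0, 1).
#' @return list with `kept` and `discarded` tables.
#' @export
filter_speeders <- function(indexed, fraction = 0.10) {
  indexed <- as_dt(indexed, "indexed responses")
  check_columns(indexed, "si", "indexed responses")
  if (fraction < 0 || fraction >= 1) {
    stop_config("filter_speeders: fraction must be in [0, 1)")
  }
  thr <- unname(quantile(indexed$si, fraction))
  bad <- indexed$si < thr
  list(kept = indexed[!bad], discarded = indexed[bad])
}

#' Classify PHQ-9 totals into severity groups
#'
#' Half-open score bands: totals below 10 are none/mild, totals in [10, 20)
#' moderate (covering the instrument's moderate and moderately-severe bands),
#' and totals of 20 or more severe.
#'
#' @param total numeric vector of PHQ-9 totals in [0, 27].
#' @return factor with levels none_mild, moderate, severe.
#' @export
classify_severity <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 27)) {
    stop_config("classify_severity: totals must lie in [0, 27]")
  }
  cls <- SEVERITY_LEVELS[findInterval(total, c(0, 10, 20))]
  factor(cls, levels = SEVERITY_LEVELS)
}

#' Binarise item scores into symptom presence
#'
#' A symptom counts as present when its (possibly fractional, averaged or
#' interpolated) daily score is strictly greater than zero.
#'
#' @param item_scores numeric vector or matrix of scores in [0, 3].
#' @return logical vector/matrix of the same shape.
#' @export
binarize_symptoms <- function(item_scores) {
  if (any(item_scores < 0 | item_scores > 3, na.rm = TRUE)) {
    stop_config("binarize_symptoms: item scores must lie in [0, 3]")
  }
  item_scores > 0
}

finalize_daily <- function(daily) {
  daily[, "total" := rowSums(as.matrix(daily[, item_cols(), with = FALSE]))]
  daily[, "severity" := classify_severity(daily$total)]
  pres <- binarize_symptoms(as.matrix(daily[, item_cols(), with = FALSE]))
  for (j in 1:9) data.table::set(daily, j = paste0("present", j), value = pres[, j])
  data.table::setcolorder(daily, c("participant_id", "date", item_cols(),
                                   "total", "interpolated", "severity",
                                   presence_cols()))
  daily[]
}

#' Aggregate filtered responses into daily symptom records
#'
#' For each participant-day with at least one response, the daily item scores
#' are per-item arithmetic means over that day's responses; the daily total
#' is their sum.
#'
#' @param responses filtered EMA response table.
#' @return daily symptom record table (observed days only,
#'   `interpolated = FALSE`).
#' @export
aggregate_daily <- function(responses) {
  responses <- as_dt(responses, "responses")
  check_columns(responses, c("participant_id", "timestamp", item_cols()),
                "EMA responses")
  responses[, "date" := as.Date(responses$timestamp)]
  daily <- responses[, lapply(.SD, mean), by = c("participant_id", "date"),
                     .SDcols = item_cols()]
  daily[, "interpolated" := FALSE]
  data.table::setorderv(daily, c("participant_id", "date"))
  finalize_daily(daily)
}

#' Fill calendar gaps by per-item linear interpolation
#'
#' Every calendar day between a participant's first and last observed day
#' receives a record; interior gaps are filled per item by linear
#' interpolation and the interpolated total is the sum of the interpolated
#' item scores. No extrapolation beyond the observed span; participants with
#' fewer than two observed days are dropped with a warning.
#'
#' @param daily observed daily symptom records from [aggregate_daily()].
#' @return dense daily symptom record table.
#' @export
interpolate_daily_items <- function(daily) {
  daily <- as_dt(daily, "daily records")
  check_columns(daily, c("participant_id", "date", item_cols()), "daily records")
  n_obs <- daily[, .N, by = "participant_id"]
  drop <- n_obs$participant_id[n_obs$N < 2L]
  if (length(drop) > 0L) {
    warning(sprintf("interpolate_daily_items: excluding %d participant(s) with < 2 observed days: %s",
                    length(drop), paste(drop, collapse = ", ")), call. = FALSE)
    daily <- daily[!daily$participant_id %in% drop]
  }
  if (nrow(daily) == 0L) {
    empty <- daily[, c("participant_id", "date", item_cols()), with = FALSE]
    empty[, "interpolated" := logical(0)]
    return(finalize_daily(empty))
  }
  fill_one <- function(sd) {
    days <- seq(min(sd$date), max(sd$date), by = "day")
    out <- data.table(date = days)
    for (j in item_cols()) {
      data.table::set(out, j = j,
                      value = approx(as.numeric(sd$date), sd[[j]],
                                     xout = as.numeric(days), rule = 1)$y)
    }
    out[, "interpolated" := !days %in% sd$date]
    out
  }
  dense <- daily[, fill_one(.SD), by = "participant_id",
                 .SDcols = c("date", item_cols())]
  finalize_daily(dense)
}

#' Run the full EMA pipeline
#'
#' reliability filter -> Speeder-Index filter -> daily aggregation ->
#' per-item linear interpolation.
#'
#' @param responses raw EMA response table.
#' @param speeder_fraction Speeder-Index quantile cutoff (default 0.10).
#' @return list with `daily` (dense daily records), `observed` (pre-
#'   interpolation records) and `counts` (kept/discarded per filter).
#' @export
process_ema <- function(responses, speeder_fraction = 0.10) {
  rel <- filter_reliability(responses)
  idx <- compute_speeder_index(rel$kept)
  spd <- filter_speeders(idx, speeder_fraction)
  observed <- aggregate_daily(spd$kept)
  daily <- interpolate_daily_items(observed)
  list(
    daily = daily,
    observed = observed,
    counts = list(
      input = nrow(as_dt(responses)),
      reliability_discarded = nrow(rel$discarded),
      speeder_discarded = nrow(spd$discarded),
      kept = nrow(spd$kept),
      observed_days = nrow(observed),
      dense_days = nrow(daily)
    )
  )
}
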