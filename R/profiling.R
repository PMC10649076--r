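# Symptom-profile representation.
#
# Each participant-day is summarised by a nine-element symptom profile
# vector SP = SH * SS (element-wise): SS, the symptom significance vector,
# is the per-participant absolute Pearson correlation between each PHQ-9
# item and the total score over the first month of self-reports; SH, the
# symptom heterogeneity vector, is the per-day model-predicted probability
# of each symptom being present. The product down-weights symptoms that are
# present but uninformative about the person's overall depression level.

#' Split daily data into the profiling month and the prediction window
#'
#' Each participant's first 30 calendar days (from their own first record)
#' form the profiling set; all later days form the prediction set.
#' Participants with fewer than 31 days of span are excluded with a
#' warning, since their prediction set would be empty.
#'
#' @param daily a per-participant-day table with `participant_id` and
#'   `date`.
#' @param month_days length of the profiling window in days (default 30).
#' @return list with `profile`, `prediction` and `excluded` (participant
#'   ids).
#' @export
split_first_month <- function(daily, month_days = 30L) {
  daily <- as_dt(daily, "daily data")
  check_columns(daily, c("participant_id", "date"), "daily data")
  daily <- data.table::copy(daily)
  daily[, "first_date" := min(date), by = "participant_id"]
  span <- daily[, .(span = as.integer(max(date) - min(date)) + 1L),
                by = "participant_id"]
  excluded <- span$participant_id[span$span < month_days + 1L]
  if (length(excluded) > 0L) {
    warning(sprintf("split_first_month: excluding %d participant(s) with < %d days of data",
                    length(excluded), month_days + 1L), call. = FALSE)
    daily <- daily[!daily$participant_id %in% excluded]
  }
  in_month1 <- as.integer(daily$date - daily$first_date) < month_days
  daily[, "first_date" := NULL]
  list(profile = daily[in_month1], prediction = daily[!in_month1],
       excluded = excluded)
}

#' Symptom significance vectors from first-month self-reports
#'
#' For each participant, `ss[j]` is the absolute Pearson correlation between
#' the daily scores of item j and the daily total score. Degenerate cases --
#' a constant item series, a constant total, or fewer than three records --
#' yield `ss[j] = 0` and are flagged, so the profile stays well defined.
#'
#' @param daily first-month daily symptom records.
#' @param observed_only if `TRUE` (default) only non-interpolated records
#'   enter the correlation, matching the use of collected self-reports.
#' @return data.table with `participant_id`, `ss1..ss9`, `n_reports` and
#'   `deg1..deg9` degenerate-case flags.
#' @export
compute_symptom_significance <- function(daily, observed_only = TRUE) {
  daily <- as_dt(daily, "daily records")
  check_columns(daily, c("participant_id", item_cols(), "total"),
                "daily records")
  if (observed_only && "interpolated" %in% names(daily)) {
    daily <- daily[!daily$interpolated]
  }
  if (nrow(daily) == 0L) {
    stop_config("compute_symptom_significance: no (observed) records supplied")
  }
  one <- function(sd) {
    n <- nrow(sd)
    ss <- numeric(9)
    deg <- logical(9)
    for (j in 1:9) {
      item <- sd[[paste0("item", j)]]
      if (n < 3L || sd(item) == 0 || sd(sd$total) == 0) {
        deg[j] <- TRUE
      } else {
        ss[j] <- abs(cor(item, sd$total))
      }
    }
    out <- as.list(c(ss, n, deg))
    names(out) <- c(ss_cols(), "n_reports", paste0("deg", 1:9))
    out
  }
  res <- daily[, one(.SD), by = "participant_id"]
  res[, "n_reports" := as.integer(n_reports)]
  for (j in paste0("deg", 1:9)) data.table::set(res, j = j,
                                                value = as.logical(res[[j]]))
  res[]
}

#' Compose symptom profiles from heterogeneity and significance
#'
#' Element-wise (Hadamard) product of the per-day symptom probability
#' vectors and the per-participant significance vectors; every element of
#' the result is bounded by both factors.
#'
#' @param sh table with `participant_id`, `date`, `p1..p9` (probabilities).
#' @param ss table with `participant_id`, `ss1..ss9`.
#' @return data.table with `participant_id`, `date`, `sp1..sp9`.
#' @export
compose_symptom_profile <- function(sh, ss) {
  sh <- as_dt(sh, "symptom heterogeneity")
  ss <- as_dt(ss, "symptom significance")
  check_columns(sh, c("participant_id", "date", prob_cols()),
                "symptom heterogeneity")
  check_columns(ss, c("participant_id", ss_cols()), "symptom significance")
  missing_p <- setdiff(unique(sh$participant_id), unique(ss$participant_id))
  if (length(missing_p) > 0L) {
    stop_config("compose_symptom_profile: no significance vector for participant(s): %s",
                paste(missing_p, collapse = ", "))
  }
  out <- ss[, c("participant_id", ss_cols()), with = FALSE][
    sh, on = "participant_id"]
  for (j in 1:9) {
    data.table::set(out, j = paste0("sp", j),
                    value = out[[paste0("p", j)]] * out[[paste0("ss", j)]])
  }
  out[, c("participant_id", "date", sp_cols()), with = FALSE]
}

#' Default symptom weights
#'
#' The DSM-5 cardinal symptoms -- depressed mood and diminished interest
#' (anhedonia), PHQ-9 items 2 and 1 -- get weight 2; all other symptoms
#' weight 1.
#'
#' @return named numeric vector of length 9.
#' @export
default_symptom_weights <- function() {
  stats::setNames(c(2, 2, rep(1, 7)), PHQ9_ITEMS)
}

#' Apply symptom weights to a profile
#'
#' In `"scale"` mode the designated profile elements are multiplied by their
#' weights (the input-scaling route used for margin-based classifiers); in
#' `"directive"` mode the weight vector itself is returned, for classifiers
#' that accept per-feature weight parameters.
#'
#' @param sp symptom profile table with `sp1..sp9`.
#' @param weights positive length-9 weight vector (default
#'   [default_symptom_weights()]).
#' @param mode `"scale"` or `"directive"`.
#' @return weighted profile table, or the validated weight vector.
#' @export
apply_symptom_weights <- function(sp, weights = default_symptom_weights(),
                                  mode = c("scale", "directive")) {
  mode <- match.arg(mode)
  if (length(weights) != 9L || any(!is.finite(weights)) || any(weights <= 0)) {
    stop_config("apply_symptom_weights: weights must be 9 positive numbers")
  }
  if (mode == "directive") return(weights)
  sp <- as_dt(sp, "symptom profile")
  check_columns(sp, sp_cols(), "symptom profile")
  out <- data.table::copy(sp)
  for (j in 1:9) {
    data.table::set(out, j = paste0("sp", j),
                    value = out[[paste0("sp", j)]] * weights[j])
  }
  out[]
}
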