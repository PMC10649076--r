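# Sensor-stream processing: range cleaning, GPS outlier removal, gap
# imputation, per-participant Box-Cox transforms, daily feature extraction
# and feature pruning.
#
# Stage order is fixed: range-clean -> GPS-clean -> impute -> Box-Cox ->
# featurise -> prune. Cleaning stages never add records; imputation never
# removes them.

#' Remove out-of-range sensor records
#'
#' A record is removed iff any of its fields lies outside the valid range
#' registered for its source (durations and counts must be non-negative,
#' coordinates on the globe, ...).
#'
#' @param records long sensor record table (`participant_id`, `source`,
#'   `timestamp`, `field`, `value`, `lat`, `lon`).
#' @param ranges valid-range table from [field_ranges()].
#' @return list with `kept`, `removed` and `counts` (removed per source).
#' @export
remove_out_of_range <- function(records, ranges = field_ranges()) {
  records <- as_dt(records, "sensor records")
  check_columns(records, c("participant_id", "source", "timestamp", "field",
                           "value"), "sensor records")
  unknown <- setdiff(unique(records$source), unique(ranges$source))
  if (length(unknown) > 0L) {
    stop_config("remove_out_of_range: unknown source(s) without a range spec: %s",
                paste(unknown, collapse = ", "))
  }
  gps <- records$source == "gps"
  bad <- rep(FALSE, nrow(records))
  if (any(gps)) {
    glat <- ranges[ranges$source == "gps" & ranges$field == "lat"]
    glon <- ranges[ranges$source == "gps" & ranges$field == "lon"]
    bad[gps] <- records$lat[gps] < glat$min | records$lat[gps] > glat$max |
      records$lon[gps] < glon$min | records$lon[gps] > glon$max
  }
  oth <- which(!gps)
  if (length(oth) > 0L) {
    m <- ranges[records[oth, c("source", "field"), with = FALSE],
                on = c("source", "field")]
    bad[oth] <- !is.na(records$value[oth]) &
      (records$value[oth] < m$min | records$value[oth] > m$max)
  }
  bad[is.na(bad)] <- FALSE
  counts <- as.data.frame(table(source = records$source[bad]))
  list(kept = records[!bad], removed = records[bad], counts = counts)
}

#' Clean GPS fixes with density-based clustering
#'
#' Runs DBSCAN per participant on (lat, lon) in degrees. The minimum cluster
#' size is derived from the minimum duration of stay at a place and the GPS
#' sampling cadence: `min_samples = ceiling(min_stay_h * 60 / interval_min)`
#' (10 points for a 2.5 h stay at a 15-minute cadence). Noise-labelled
#' points are removed; cluster labels are retained for the location
#' features.
#'
#' @param points GPS record rows (must carry `participant_id`, `timestamp`,
#'   `lat`, `lon`).
#' @param eps DBSCAN radius in degrees (default 0.0005, about 55 m).
#' @param min_stay_h minimum stay duration defining a place, hours.
#' @param interval_min GPS collection cadence, minutes.
#' @return list with `kept` (points plus `cluster` column), `removed` and
#'   `min_samples`.
#' @export
clean_gps <- function(points, eps = 0.0005, min_stay_h = 2.5,
                      interval_min = 15) {
  points <- as_dt(points, "GPS points")
  check_columns(points, c("participant_id", "timestamp", "lat", "lon"),
                "GPS points")
  min_samples <- as.integer(ceiling(min_stay_h * 60 / interval_min))
  points <- data.table::copy(points)
  points[, "cluster" := 0L]
  for (p in unique(points$participant_id)) {
    idx <- which(points$participant_id == p)
    if (length(idx) < min_samples) {
      warning(sprintf("clean_gps: participant %s has fewer than %d points; all flagged noise",
                      p, min_samples), call. = FALSE)
      next
    }
    points$cluster[idx] <- dbscan_points(points$lat[idx], points$lon[idx],
                                         eps, min_samples)
  }
  list(kept = points[points$cluster > 0L],
       removed = points[points$cluster == 0L],
       min_samples = min_samples)
}

#' Impute missing ticks of interval-based streams
#'
#' For interval-cadence sources only, missing ticks between a participant's
#' first and last observed tick are filled by per-field linear
#' interpolation on the cadence grid; event-based sources pass through
#' untouched. Imputed rows carry `imputed = TRUE` and no record id.
#'
#' @param records long sensor record table (post cleaning).
#' @param registry source registry from [source_registry()].
#' @return record table with imputed rows appended.
#' @export
impute_interval_gaps <- function(records, registry) {
  records <- as_dt(records, "sensor records")
  out <- data.table::copy(records)
  out[, "imputed" := FALSE]
  interval_src <- registry[registry$cadence == "interval"]
  blocks <- list(out)
  for (k in seq_len(nrow(interval_src))) {
    src <- interval_src$source[k]
    step_s <- interval_src$interval_min[k] * 60
    sub <- records[records$source == src]
    if (nrow(sub) == 0L) next
    if (src == "gps") {
      fill <- sub[, impute_series(.SD, step_s, c("lat", "lon")),
                  by = "participant_id"]
      if (nrow(fill) == 0L) next
      fill[, "field" := "location"]
      fill[, "value" := NA_real_]
    } else {
      fill <- sub[, impute_series(.SD, step_s, "value"),
                  by = c("participant_id", "field")]
      if (nrow(fill) == 0L) next
      fill[, "lat" := NA_real_]
      fill[, "lon" := NA_real_]
    }
    fill[, "source" := src]
    fill[, "record_id" := NA_integer_]
    fill[, "tag" := NA_character_]
    if ("cluster" %in% names(out)) fill[, "cluster" := NA_integer_]
    fill[, "imputed" := TRUE]
    blocks[[length(blocks) + 1L]] <- fill
  }
  res <- data.table::rbindlist(blocks, use.names = TRUE, fill = TRUE)
  data.table::setorderv(res, c("participant_id", "source", "timestamp", "field"))
  res[]
}

# interpolate the named columns of one (participant[, field]) series onto its
# cadence grid; returns only the previously missing ticks
impute_series <- function(sd, step_s, value_cols) {
  ts <- as.numeric(sd$timestamp)
  grid <- seq(min(ts), max(ts), by = step_s)
  miss <- setdiff(grid, ts)
  if (length(miss) == 0L) {
    empty <- data.table(timestamp = sd$timestamp[0])
    for (v in value_cols) data.table::set(empty, j = v, value = numeric(0))
    return(empty)
  }
  out <- data.table(timestamp = as.POSIXct(miss, tz = "",
                                           origin = "1970-01-01"))
  o <- order(ts)
  for (v in value_cols) {
    data.table::set(out, j = v, value = approx(ts[o], sd[[v]][o], xout = miss,
                                               rule = 1)$y)
  }
  out
}

# profile log-likelihood of the Box-Cox parameter for an i.i.d. normal model
bc_loglik <- function(lambda, y, log_y_sum) {
  yt <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  n <- length(y)
  -n / 2 * log(pop_var(yt)) + (lambda - 1) * log_y_sum
}

bc_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Box-Cox transform sensor values per participant
#'
#' Estimates the Box-Cox exponent by profile maximum likelihood separately
#' for each participant's series of each source field and applies the
#' transform. Non-positive series are shifted by `1 - min` before fitting;
#' the applied (lambda, shift) pairs are returned for reproducibility.
#' Latitude/longitude are never transformed (the location features need raw
#' coordinates) and constant series are skipped and flagged.
#'
#' @param records long sensor record table.
#' @param lambda_range search interval for the exponent.
#' @return list with `records` (transformed) and `params` (one row per
#'   participant x source x field: `lambda`, `shift`, `skipped`).
#' @export
transform_boxcox <- function(records, lambda_range = c(-2, 2)) {
  records <- as_dt(records, "sensor records")
  out <- data.table::copy(records)
  el <- which(out$source != "gps" & !is.na(out$value))
  gkey <- paste(out$participant_id[el], out$source[el], out$field[el],
                sep = "\r")
  idx_by_group <- split(el, gkey)
  keys <- do.call(rbind, strsplit(names(idx_by_group), "\r", fixed = TRUE))
  params <- data.table(participant_id = keys[, 1], source = keys[, 2],
                       field = keys[, 3], lambda = NA_real_,
                       shift = NA_real_, skipped = FALSE)
  for (g in seq_along(idx_by_group)) {
    idx <- idx_by_group[[g]]
    y <- out$value[idx]
    if (length(unique(y)) < 2L) {
      params$skipped[g] <- TRUE
      next
    }
    shift <- if (min(y) <= 0) 1 - min(y) else 0
    ys <- y + shift
    lsum <- sum(log(ys))
    opt <- optimize(bc_loglik, lambda_range, y = ys, log_y_sum = lsum,
                    maximum = TRUE)
    params$lambda[g] <- opt$maximum
    params$shift[g] <- shift
    data.table::set(out, i = idx, j = "value",
                    value = bc_transform(ys, opt$maximum))
  }
  data.table::setorderv(params, c("participant_id", "source", "field"))
  list(records = out, params = params[])
}

# ---- daily feature extraction ----------------------------------------------

day_dwell_hours <- function(ts) {
  # apportion the 24 h day to samples: sample i holds from its own time to
  # the next sample (or end of day); the lead-in from midnight goes to the
  # first sample, so a fully covered day sums to 24 h
  t <- as.numeric(ts)
  day_start <- as.numeric(as.POSIXct(paste(as.Date(ts[1]), "00:00:00"),
                                     tz = ""))
  dwell <- diff(c(t, day_start + 86400))
  dwell[1] <- dwell[1] + (t[1] - day_start)
  dwell / 3600
}

#' Daily location features from cluster-labelled GPS points
#'
#' The home cluster is the cluster holding the most samples between 00:00
#' and 06:00 over the whole observation period; the work cluster is the
#' different cluster with the most weekday samples between 09:00 and 17:00.
#' Per day: hours at home/work/other places (apportioned by inter-sample
#' interval), total travelled distance and maximum distance from home
#' (great-circle), number of distinct clusters visited, and the standard
#' deviation of consecutive displacements.
#'
#' @param points cluster-labelled GPS points from [clean_gps()] (rows with
#'   `cluster = NA`, e.g. imputed ticks, are assigned to the nearest cluster
#'   centroid within `eps`, otherwise counted as other places).
#' @param eps cluster radius in degrees used for the nearest-centroid
#'   assignment.
#' @return data.table keyed (participant_id, date) with the seven location
#'   feature columns.
#' @export
extract_location_features <- function(points, eps = 0.0005) {
  points <- as_dt(points, "GPS points")
  check_columns(points, c("participant_id", "timestamp", "lat", "lon",
                          "cluster"), "GPS points")
  points <- data.table::copy(points)
  points[, "date" := as.Date(points$timestamp)]
  points[, "hour" := as.numeric(format(points$timestamp, "%H")) +
           as.numeric(format(points$timestamp, "%M")) / 60]
  points[, "weekday" := !format(points$date, "%u") %in% c("6", "7")]

  one_participant <- function(sd) {
    lab <- sd[!is.na(sd$cluster) & sd$cluster > 0L]
    if (nrow(lab) == 0L) return(NULL)
    cent <- lab[, .(clat = mean(lat), clon = mean(lon), n = .N),
                by = "cluster"]
    night <- lab[lab$hour < 6, .N, by = "cluster"]
    home <- if (nrow(night) > 0L) night$cluster[which.max(night$N)] else
      cent$cluster[which.max(cent$n)]
    workday <- lab[lab$weekday & lab$hour >= 9 & lab$hour < 17 &
                     lab$cluster != home, .N, by = "cluster"]
    work <- if (nrow(workday) > 0L) workday$cluster[which.max(workday$N)] else
      NA_integer_
    # fill unlabelled (imputed) points from the nearest centroid within eps
    sd <- data.table::copy(sd)
    na_idx <- which(is.na(sd$cluster))
    if (length(na_idx) > 0L) {
      d2 <- outer(sd$lat[na_idx], cent$clat, "-")^2 +
        outer(sd$lon[na_idx], cent$clon, "-")^2
      nearest <- apply(d2, 1L, which.min)
      ok <- d2[cbind(seq_along(na_idx), nearest)] <= eps^2
      sd$cluster[na_idx] <- ifelse(ok, cent$cluster[nearest], 0L)
    }
    home_lat <- cent$clat[cent$cluster == home]
    home_lon <- cent$clon[cent$cluster == home]
    one_day <- function(dd) {
      o <- order(dd$timestamp)
      dd <- dd[o]
      dwell <- day_dwell_hours(dd$timestamp)
      disp <- if (nrow(dd) > 1L) {
        geosphere::distHaversine(cbind(dd$lon[-nrow(dd)], dd$lat[-nrow(dd)]),
                                 cbind(dd$lon[-1], dd$lat[-1])) / 1000
      } else {
        numeric(0)
      }
      list(
        loc_time_home_h = sum(dwell[dd$cluster == home]),
        loc_time_work_h = if (is.na(work)) 0 else
          sum(dwell[dd$cluster == work]),
        loc_time_other_h = sum(dwell[dd$cluster != home &
                                       (is.na(work) | dd$cluster != work)]),
        loc_total_distance_km = sum(disp),
        loc_max_home_distance_km = max(geosphere::distHaversine(
          cbind(dd$lon, dd$lat), c(home_lon, home_lat)) / 1000),
        loc_visited_places_n = as.numeric(length(unique(
          dd$cluster[dd$cluster > 0L]))),
        loc_displacement_sd_km = if (length(disp) > 0L) pop_sd(disp) else 0
      )
    }
    sd[, one_day(.SD), by = "date"]
  }
  out <- points[, one_participant(.SD), by = "participant_id"]
  out[]
}

mean_var_features <- function(dt, prefix) {
  out <- dt[, .(m = mean(value, na.rm = TRUE), v = pop_var(value)),
            by = c("participant_id", "date")]
  data.table::setnames(out, c("m", "v"),
                       paste0(prefix, c("_mean", "_var")))
  out
}

count_feature <- function(dt, name, expr_sum = TRUE) {
  out <- if (expr_sum) {
    dt[, .(x = sum(value, na.rm = TRUE)), by = c("participant_id", "date")]
  } else {
    dt[, .(x = as.numeric(.N)), by = c("participant_id", "date")]
  }
  data.table::setnames(out, "x", name)
  out
}

#' Extract daily features from preprocessed sensor records
#'
#' Computes the platform's daily feature schema (see [feature_schema()]) over
#' 24-hour windows: duration sources yield mean and population variance of
#' episode durations, value sources mean and population variance of
#' measurements, quantity sources cumulative counts; GPS yields the location
#' features; demographics contribute gender and age group, the calendar the
#' day of week. Days without data from a source leave that source's cells
#' missing.
#'
#' @param records cleaned/imputed/transformed long record table (GPS rows
#'   cluster-labelled).
#' @param demographics table with `participant_id`, `gender`, `age`.
#' @param platform `"android"` or `"ios"`.
#' @param app_significance category-significance map, see
#'   [app_significance_map()].
#' @return data.table keyed (participant_id, date) with exactly the schema
#'   columns.
#' @export
extract_daily_features <- function(records, demographics,
                                   platform = c("android", "ios"),
                                   app_significance = app_significance_map()) {
  platform <- match.arg(platform)
  records <- as_dt(records, "sensor records")
  demographics <- as_dt(demographics, "demographics")
  check_columns(demographics, c("participant_id", "gender", "age"),
                "demographics")
  records <- data.table::copy(records)
  records[, "date" := as.Date(records$timestamp)]
  schema <- feature_schema(platform)
  keys <- records[, .(date = seq(min(date), max(date), by = "day")),
                  by = "participant_id"]

  feats <- list()
  addf <- function(f) feats[[length(feats) + 1L]] <<- f
  src <- function(s) records[records$source == s]

  if ("app_usage" %in% schema$source) {
    app <- src("app_usage")
    app[, "category" := vapply(strsplit(app$tag, "|", fixed = TRUE), `[`, "",
                               2L)]
    sig_cats <- app_significance$category[app_significance$significant]
    for (g in c(APP_CATEGORIES, "significant", "nonsignificant")) {
      sub <- switch(g,
        significant = app[app$category %in% sig_cats],
        nonsignificant = app[!app$category %in% sig_cats],
        app[app$category == g])
      addf(mean_var_features(sub, sprintf("app_%s_duration", g)))
    }
  }
  if ("call_log" %in% schema$source) {
    calls <- src("call_log")
    for (d in c("missed", "incoming", "outgoing")) {
      addf(count_feature(calls[calls$tag == d], sprintf("calls_%s_n", d),
                         expr_sum = FALSE))
    }
    for (d in c("incoming", "outgoing")) {
      addf(mean_var_features(calls[calls$tag == d],
                             sprintf("calls_%s_duration", d)))
    }
  }
  if ("gps" %in% schema$source) {
    gps <- src("gps")
    if (nrow(gps) > 0L) {
      if (!"cluster" %in% names(gps)) gps[, "cluster" := NA_integer_]
      addf(extract_location_features(gps))
    }
  }
  if ("gravity" %in% schema$source) {
    grav <- src("gravity")
    for (ax in c("x", "y", "z")) {
      addf(mean_var_features(grav[grav$field == paste0("gravity_", ax)],
                             sprintf("gravity_%s", ax)))
    }
  }
  if ("keystroke" %in% schema$source) {
    keys_dt <- src("keystroke")
    addf(count_feature(keys_dt[keys_dt$field == "presses"], "keys_pressed_n"))
    addf(count_feature(keys_dt[keys_dt$field == "backspaces"],
                       "keys_backspace_n"))
    addf(count_feature(keys_dt[keys_dt$field == "autocorrections"],
                       "keys_autocorrect_n"))
    uapp <- keys_dt[!is.na(keys_dt$tag),
                    .(keys_unique_apps_n = as.numeric(data.table::uniqueN(
                      vapply(strsplit(tag, "|", fixed = TRUE), `[`, "", 1L)))),
                    by = c("participant_id", "date")]
    addf(uapp)
    typ <- keys_dt[keys_dt$field == "duration_s"]
    typ[, "category" := vapply(strsplit(typ$tag, "|", fixed = TRUE), `[`, "",
                               2L)]
    sig_cats <- app_significance$category[app_significance$significant]
    addf(mean_var_features(typ[typ$category %in% sig_cats],
                           "typing_sig_duration"))
    addf(mean_var_features(typ[!typ$category %in% sig_cats],
                           "typing_nonsig_duration"))
  }
  if ("light" %in% schema$source) {
    addf(mean_var_features(src("light"), "light"))
  }
  if ("microphone" %in% schema$source) {
    mic <- src("microphone")
    addf(mean_var_features(mic[mic$field == "energy"], "sound_energy"))
    addf(count_feature(mic[mic$field == "pitch_detected"], "pitch_detected_n"))
  }
  if ("notifications" %in% schema$source) {
    ntf <- src("notifications")
    addf(count_feature(ntf[ntf$field == "event"], "notif_arrived_n",
                       expr_sum = FALSE))
    addf(count_feature(ntf[ntf$field == "decision_time_s"], "notif_clicked_n",
                       expr_sum = FALSE))
    uapp <- ntf[!is.na(ntf$tag),
                .(notif_unique_apps_n = as.numeric(data.table::uniqueN(tag))),
                by = c("participant_id", "date")]
    addf(uapp)
    addf(mean_var_features(ntf[ntf$field == "decision_time_s"],
                           "notif_decision_time"))
  }
  if ("pedometer" %in% schema$source) {
    addf(count_feature(src("pedometer"), "steps_n"))
  }
  if ("physical_activity" %in% schema$source) {
    act <- src("physical_activity")
    addf(mean_var_features(act[act$tag %in% ACTIVITY_ACTIVE],
                           "activity_active_duration"))
    addf(mean_var_features(act[act$tag %in% ACTIVITY_INACTIVE],
                           "activity_inactive_duration"))
  }
  if ("screen" %in% schema$source) {
    addf(mean_var_features(src("screen"), "screen_unlocked_duration"))
  }
  if ("stored_media" %in% schema$source) {
    med <- src("stored_media")[, .(media_images_mean = mean(value, na.rm = TRUE)),
                               by = c("participant_id", "date")]
    addf(med)
  }
  if ("wifi" %in% schema$source) {
    wf <- src("wifi")[, .(wifi_ap_mean = mean(value, na.rm = TRUE)),
                      by = c("participant_id", "date")]
    addf(wf)
  }

  mat <- keys
  for (f in feats) {
    if (!is.null(f) && nrow(f) > 0L) mat <- f[mat, on = c("participant_id", "date")]
  }
  # calendar + demographics
  mat[, "day_of_week" := as.integer(format(mat$date, "%u"))]
  demo <- data.table::copy(demographics)
  demo[, "age_group" := AGE_GROUP_LEVELS[findInterval(demo$age, c(0, 31, 46))]]
  mat <- demo[, c("participant_id", "gender", "age_group"),
              with = FALSE][mat, on = "participant_id"]
  for (col in setdiff(schema$column, names(mat))) {
    data.table::set(mat, j = col, value = NA_real_)
  }
  data.table::setcolorder(mat, c("participant_id", "date", schema$column))
  data.table::setorderv(mat, c("participant_id", "date"))
  mat[]
}

#' Prune quasi-constant and poorly observed features
#'
#' Drops quasi-constant feature columns -- those whose most frequent value
#' covers more than `1 - var_threshold` of the observed cells (the
#' scale-free low-variability test; a strictly constant column is the
#' limiting case) -- then columns whose missing fraction exceeds
#' `miss_threshold`. Identifier, demographic and calendar columns are
#' exempt.
#'
#' @param mat feature matrix from [extract_daily_features()].
#' @param var_threshold low-variability threshold: the minimum share of
#'   observed cells that must differ from the modal value (default 0.05).
#' @param miss_threshold maximum tolerated missing fraction.
#' @return pruned matrix; dropped column names in attributes
#'   `dropped_variance` and `dropped_missing`.
#' @export
prune_features <- function(mat, var_threshold = 0.05, miss_threshold = 0.20) {
  mat <- as_dt(mat, "feature matrix")
  exempt <- c("participant_id", "date", "gender", "age_group", "day_of_week")
  num_cols <- setdiff(names(mat), exempt)
  modal_share <- vapply(num_cols, function(cn) {
    x <- mat[[cn]]
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(1)
    max(tabulate(match(x, unique(x)))) / length(x)
  }, numeric(1))
  drop_var <- num_cols[modal_share > 1 - var_threshold]
  keep <- setdiff(num_cols, drop_var)
  miss_frac <- vapply(keep, function(cn) mean(is.na(mat[[cn]])), numeric(1))
  drop_miss <- keep[miss_frac > miss_threshold]
  out <- mat[, setdiff(names(mat), c(drop_var, drop_miss)), with = FALSE]
  data.table::setattr(out, "dropped_variance", drop_var)
  data.table::setattr(out, "dropped_missing", drop_miss)
  out
}

#' Encode a feature matrix for model fitting
#'
#' Maps the categorical schema columns to numeric codes (gender: female = 1;
#' age group: 1-3 ordinal; day of week already 1-7) and returns a numeric
#' matrix aligned with the (participant_id, date) keys.
#'
#' @param mat (pruned) feature matrix.
#' @return list with `keys` (participant_id, date) and `x` (numeric matrix).
#' @export
encode_feature_matrix <- function(mat) {
  mat <- as_dt(mat, "feature matrix")
  keys <- mat[, c("participant_id", "date"), with = FALSE]
  x <- data.table::copy(mat)[, c("participant_id", "date") := NULL]
  if ("gender" %in% names(x)) {
    data.table::set(x, j = "gender",
                    value = as.numeric(x$gender == "female"))
  }
  if ("age_group" %in% names(x)) {
    data.table::set(x, j = "age_group",
                    value = as.numeric(match(x$age_group, AGE_GROUP_LEVELS)))
  }
  list(keys = keys, x = as.matrix(x))
}

#' Run the full sensor pipeline
#'
#' range-clean -> GPS-clean -> impute -> Box-Cox -> featurise -> prune.
#'
#' @param records raw long sensor record table.
#' @param demographics demographics table.
#' @param platform `"android"` or `"ios"`.
#' @param eps,min_stay_h DBSCAN parameters for [clean_gps()].
#' @param var_threshold,miss_threshold pruning thresholds.
#' @return list with `features` (pruned), `features_full` (pre-pruning),
#'   `boxcox_params`, `gps` (clean_gps output) and `counts`.
#' @export
process_sensors <- function(records, demographics,
                            platform = c("android", "ios"),
                            eps = 0.0005, min_stay_h = 2.5,
                            var_threshold = 0.05, miss_threshold = 0.20) {
  platform <- match.arg(platform)
  registry <- source_registry(platform)
  rng <- remove_out_of_range(records)
  gps_rows <- rng$kept$source == "gps"
  gps_interval <- registry$interval_min[registry$source == "gps"]
  gps <- clean_gps(rng$kept[gps_rows], eps = eps, min_stay_h = min_stay_h,
                   interval_min = gps_interval)
  cleaned <- data.table::rbindlist(
    list(rng$kept[!gps_rows], gps$kept), use.names = TRUE, fill = TRUE)
  imputed <- impute_interval_gaps(cleaned, registry)
  bc <- transform_boxcox(imputed)
  features_full <- extract_daily_features(bc$records, demographics, platform)
  features <- prune_features(features_full, var_threshold, miss_threshold)
  list(
    features = features,
    features_full = features_full,
    boxcox_params = bc$params,
    gps = gps,
    counts = list(
      input = nrow(as_dt(records)),
      out_of_range_removed = nrow(rng$removed),
      gps_noise_removed = nrow(gps$removed),
      gps_min_samples = gps$min_samples,
      imputed_rows = sum(imputed$imputed),
      features_dropped_variance = length(attr(features, "dropped_variance")),
      features_dropped_missing = length(attr(features, "dropped_missing"))
    )
  )
}
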