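# Synthetic cohort simulator.
#
# Generates seeded cohorts whose EMA answers and sensor streams share a known
# latent symptom structure: each participant carries nine latent symptom
# intensity trajectories (AR(1) around a severity-group mean, on the 0-3 PHQ
# item scale) which drive both the questionnaire answers and, through a
# loading matrix, the daily rates of event-based sensor streams and the
# mobility pattern. Every planted artefact (careless trap answers, speeder
# responses, GPS outliers, negative durations, missing spans) is recorded in
# a ground-truth block so downstream filters can be validated exactly.

#' Default symptom-to-sensor loading matrix
#'
#' Rows are the nine PHQ-9 symptoms, columns the platform's analysed
#' event-coupled sources. Entry (j, s) is the log-linear effect of symptom
#' j's daily intensity on source s's event rate; negative loadings encode
#' behavioural withdrawal (fewer steps, fewer calls) with rising symptoms.
#'
#' @param platform `"android"` or `"ios"`.
#' @return 9 x n_sources numeric matrix with dimnames.
#' @export
default_loading_matrix <- function(platform = c("android", "ios")) {
  platform <- match.arg(platform)
  sources <- unique(source_registry(platform)$source)
  L <- matrix(0, nrow = 9L, ncol = length(sources),
              dimnames = list(PHQ9_ITEMS, sources))
  set_l <- function(item, source, value) {
    if (source %in% sources) L[item, source] <<- value
  }
  set_l("diminished_interest", "app_usage", -0.10)
  set_l("diminished_interest", "notifications", -0.10)
  set_l("depressed_mood", "call_log", -0.15)
  set_l("depressed_mood", "screen", 0.10)
  set_l("sleep_problems", "screen", 0.10)
  set_l("fatigue", "pedometer", -0.20)
  set_l("fatigue", "physical_activity", -0.15)
  set_l("psychomotor_change", "pedometer", -0.15)
  L
}

#' Build a validated simulation configuration
#'
#' @param n_participants number of participants.
#' @param n_days days of follow-up per participant (>= 31 so a first-month
#'   profiling window plus a prediction window exist; default 90, the study
#'   length).
#' @param platform `"android"` or `"ios"`; fixes the simulated source set.
#' @param ema_period_days days between EMA days (default 3: one EMA day,
#'   two-day interval).
#' @param ema_slots clock times ("HH:MM") of the within-day EMA prompts.
#' @param symptom_ar_coefficient AR(1) coefficient of the latent symptom
#'   trajectories, in [0, 1).
#' @param symptom_noise_sd innovation SD of the latent AR(1); scalar or
#'   length 9 (per symptom). In factor mode (see `factor_loadings`) the
#'   first element is the innovation SD of the common factor. Must be > 0.
#' @param group_means latent severity-group means (none/mild, moderate,
#'   severe) on the 0-3 item scale; per-item means in independent mode, the
#'   common-factor means in factor mode.
#' @param factor_loadings optional length-9 vector switching the latent
#'   model to a single-factor structure: item j follows
#'   `intercept_j + loading_j * g + e_j` around a severity-group factor
#'   mean, where g is the participant's AR(1) depression factor. `NULL`
#'   (default) keeps nine independent AR(1) trajectories.
#' @param factor_unique_sd per-item unique noise SD in factor mode.
#' @param item_intercepts per-item intercepts in factor mode.
#' @param symptom_effect_cap saturation point (item scale) of the
#'   behavioural dose-response: latent intensities are capped at this value
#'   before entering the sensor loading term, emulating the floor effect of
#'   behavioural withdrawal (activity cannot drop below none). `Inf` means
#'   a linear response.
#' @param severity_group_fractions length-3 fractions (none/mild, moderate,
#'   severe) summing to 1.
#' @param speeder_fraction fraction of EMA responses planted as implausibly
#'   fast "speeder" responses.
#' @param trap_error_fraction fraction of EMA responses whose trap answer is
#'   planted >= 2 points away from item 2 (careless responding).
#' @param sensor_outlier_rate fraction of duration records planted negative
#'   and of GPS points displaced far from every cluster.
#' @param sensor_missing_rate probability that a given participant-source-day
#'   of an interval stream contains a contiguous missing span.
#' @param participant_rate_sd log-scale SD of per-participant base-rate
#'   multipliers for event sources (device and lifestyle heterogeneity:
#'   people differ widely in how much they call, type or unlock their
#'   phone, independently of symptoms).
#' @param symptom_sensor_loading_matrix 9 x n_sources loading matrix; see
#'   [default_loading_matrix()].
#' @param start_date first study day (all participants start together).
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   the configuration including the seed.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_participants,
                              n_days = 90L,
                              platform = c("android", "ios"),
                              ema_period_days = 3L,
                              ema_slots = c("10:00", "14:00", "18:00"),
                              symptom_ar_coefficient = 0.8,
                              symptom_noise_sd = 0.3,
                              group_means = c(0.50, 1.55, 2.40),
                              factor_loadings = NULL,
                              factor_unique_sd = 0.3,
                              item_intercepts = 0,
                              symptom_effect_cap = Inf,
                              severity_group_fractions = c(0.6, 0.3, 0.1),
                              speeder_fraction = 0.05,
                              trap_error_fraction = 0.03,
                              sensor_outlier_rate = 0.02,
                              sensor_missing_rate = 0.05,
                              participant_rate_sd = 0.4,
                              symptom_sensor_loading_matrix = NULL,
                              start_date = as.Date("2021-07-01"),
                              seed = 1L) {
  platform <- match.arg(platform)
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop_config("invalid configuration: n_participants must be >= 1")
  }
  if (!is.numeric(n_days) || n_days < 31) {
    stop_config("invalid configuration: n_days must be >= 31 (first-month split)")
  }
  if (!is.numeric(ema_period_days) || ema_period_days < 1) {
    stop_config("invalid configuration: ema_period_days must be >= 1")
  }
  if (symptom_ar_coefficient < 0 || symptom_ar_coefficient >= 1) {
    stop_config("invalid configuration: symptom_ar_coefficient must be in [0, 1)")
  }
  if (!length(symptom_noise_sd) %in% c(1L, 9L) || any(symptom_noise_sd <= 0)) {
    stop_config("invalid configuration: symptom_noise_sd must be > 0 (length 1 or 9)")
  }
  if (length(severity_group_fractions) != 3L ||
      any(severity_group_fractions < 0) ||
      abs(sum(severity_group_fractions) - 1) > 1e-9) {
    stop_config("invalid configuration: severity_group_fractions must be 3 non-negative values summing to 1")
  }
  if (length(group_means) != 3L || any(group_means < 0 | group_means > 3)) {
    stop_config("invalid configuration: group_means must be 3 values in [0, 3]")
  }
  if (!is.null(factor_loadings) &&
      (length(factor_loadings) != 9L || any(factor_loadings <= 0))) {
    stop_config("invalid configuration: factor_loadings must be 9 positive values")
  }
  if (any(factor_unique_sd < 0) || !length(factor_unique_sd) %in% c(1L, 9L)) {
    stop_config("invalid configuration: factor_unique_sd must be >= 0 (length 1 or 9)")
  }
  if (!is.numeric(symptom_effect_cap) || symptom_effect_cap <= 0) {
    stop_config("invalid configuration: symptom_effect_cap must be > 0")
  }
  if (!is.numeric(participant_rate_sd) || participant_rate_sd < 0) {
    stop_config("invalid configuration: participant_rate_sd must be >= 0")
  }
  for (f in c("speeder_fraction", "trap_error_fraction", "sensor_outlier_rate",
              "sensor_missing_rate")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v >= 1) {
      stop_config("invalid configuration: %s must be in [0, 1)", f)
    }
  }
  sources <- unique(source_registry(platform)$source)
  L <- symptom_sensor_loading_matrix %||% default_loading_matrix(platform)
  if (!is.matrix(L) || nrow(L) != 9L || ncol(L) != length(sources)) {
    stop_config(
      "invalid configuration: symptom_sensor_loading_matrix must be 9 x %d for platform '%s'",
      length(sources), platform)
  }
  if (is.null(colnames(L))) colnames(L) <- sources
  if (!setequal(colnames(L), sources)) {
    stop_config("invalid configuration: loading matrix columns must be the platform sources")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    platform = platform,
    ema_period_days = as.integer(ema_period_days),
    ema_slots = ema_slots,
    symptom_ar_coefficient = symptom_ar_coefficient,
    symptom_noise_sd = rep_len(symptom_noise_sd, 9L),
    group_means = stats::setNames(group_means, SEVERITY_LEVELS),
    factor_loadings = factor_loadings,
    factor_unique_sd = rep_len(factor_unique_sd, 9L),
    item_intercepts = rep_len(item_intercepts, 9L),
    symptom_effect_cap = symptom_effect_cap,
    severity_group_fractions = severity_group_fractions,
    speeder_fraction = speeder_fraction,
    trap_error_fraction = trap_error_fraction,
    sensor_outlier_rate = sensor_outlier_rate,
    sensor_missing_rate = sensor_missing_rate,
    participant_rate_sd = participant_rate_sd,
    symptom_sensor_loading_matrix = L[, sources, drop = FALSE],
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Exact group counts from fractions: cumulative rounding so counts sum to n
# and rounding-free fractions give exact counts.
group_counts <- function(n, fractions) {
  cum <- round(cumsum(fractions) * n)
  counts <- diff(c(0L, cum))
  stats::setNames(as.integer(counts), SEVERITY_LEVELS)
}

simulate_demographics <- function(config) {
  n <- config$n_participants
  counts <- group_counts(n, config$severity_group_fractions)
  # age groups populated by design: 65 / 25 / 10 percent young / middle / older
  age_counts <- group_counts(n, c(0.65, 0.25, 0.10))
  age_group <- rep(AGE_GROUP_LEVELS, times = age_counts)
  age_lo <- c(18L, 31L, 46L)[match(age_group, AGE_GROUP_LEVELS)]
  age_hi <- c(30L, 45L, 61L)[match(age_group, AGE_GROUP_LEVELS)]
  dt <- data.table(
    participant_id = sprintf("P%03d", seq_len(n)),
    gender = ifelse(runif(n) < 0.63, "female", "male"),
    age = as.integer(floor(runif(n, age_lo, age_hi + 1L))),
    severity_group = rep(SEVERITY_LEVELS, times = counts)
  )
  dt[, "age_group" := AGE_GROUP_LEVELS[findInterval(dt$age, c(0, 31, 46))]]
  dt[]
}

ar1_matrix <- function(n, d, mu, phi, sd_innov, lo = 0, hi = 3) {
  # stationary start, then AR(1) recursion; clipped to the given band
  sd_stat <- sd_innov / sqrt(1 - phi^2)
  x <- matrix(NA_real_, nrow = n, ncol = d)
  x[, 1L] <- pmin(hi, pmax(lo, mu + rnorm(n, 0, sd_stat)))
  for (t in 2:d) {
    x[, t] <- pmin(hi, pmax(lo, mu + phi * (x[, t - 1L] - mu) +
                                 rnorm(n, 0, sd_innov)))
  }
  x
}

simulate_latent <- function(config, demographics) {
  n <- config$n_participants
  d <- config$n_days
  phi <- config$symptom_ar_coefficient
  sds <- config$symptom_noise_sd
  mu_p <- unname(config$group_means[demographics$severity_group])  # length n
  out <- vector("list", 9L)
  if (is.null(config$factor_loadings)) {
    # nine independent per-symptom AR(1) trajectories around the group mean
    for (j in 1:9) {
      x <- ar1_matrix(n, d, mu_p, phi, sds[j])
      out[[j]] <- as.vector(t(x))  # participant-major, day within participant
    }
  } else {
    # single-factor structure: a common AR(1) depression factor per
    # participant; items load on it with item-specific unique noise
    g <- ar1_matrix(n, d, mu_p, phi, sds[1L])
    for (j in 1:9) {
      x <- config$item_intercepts[j] + config$factor_loadings[j] * g +
        matrix(rnorm(n * d, 0, config$factor_unique_sd[j]), n, d)
      out[[j]] <- as.vector(t(pmin(3, pmax(0, x))))
    }
  }
  latent <- data.table(
    participant_id = rep(demographics$participant_id, each = d),
    day = rep(seq_len(d), times = n),
    date = rep(config$start_date + (seq_len(d) - 1L), times = n)
  )
  for (j in 1:9) data.table::set(latent, j = paste0("i", j), value = out[[j]])
  latent[]
}

#' Render EMA responses from latent symptom states
#'
#' EMAs fall every `ema_period_days` days on the configured clock slots.
#' Item answers are the latent intensities plus discretisation noise, rounded
#' to the 0-3 scale. A planted fraction of responses get a trap answer at
#' least two points away from item 2, and a planted fraction get implausibly
#' short durations (speeders).
#'
#' @param latent latent-state table from the simulator.
#' @param config a `sim_config`.
#' @return list with `ema` (response table) and `truth` (planted
#'   `trap_errors` / `speeders` response ids).
#' @export
render_ema_responses <- function(latent, config) {
  sched_days <- seq(1L, config$n_days, by = config$ema_period_days)
  slots <- config$ema_slots
  lat <- as_dt(latent, "latent")[day %in% sched_days]
  ema <- lat[rep(seq_len(nrow(lat)), each = length(slots))]
  ema[, "slot" := rep(slots, times = nrow(lat))]
  ema[, "timestamp" := as.POSIXct(paste(ema$date, ema$slot), tz = "",
                                  format = "%Y-%m-%d %H:%M")]
  nr <- nrow(ema)
  for (j in 1:9) {
    sc <- as.integer(pmin(3, pmax(0, round(ema[[paste0("i", j)]] +
                                             rnorm(nr, 0, 0.25)))))
    data.table::set(ema, j = paste0("item", j), value = sc)
  }
  # trap question: paraphrase of item 2; planted careless answers differ by 2
  trap <- ema$item2
  bad <- runif(nr) < config$trap_error_fraction
  trap[bad] <- ifelse(ema$item2[bad] >= 2L, ema$item2[bad] - 2L,
                      ema$item2[bad] + 2L)
  ema[, "trap" := as.integer(trap)]
  # durations: lognormal around one minute; speeders uniformly 3-15 s
  dur <- rlnorm(nr, meanlog = log(60), sdlog = 0.35)
  fast <- runif(nr) < config$speeder_fraction
  dur[fast] <- runif(sum(fast), 3, 15)
  ema[, "duration_s" := dur]
  ema[, "response_id" := sprintf("R%06d", seq_len(nr))]
  keep <- c("response_id", "participant_id", "timestamp", item_cols(),
            "trap", "duration_s")
  list(
    ema = ema[, keep, with = FALSE],
    truth = list(trap_errors = ema$response_id[bad],
                 speeders = ema$response_id[fast])
  )
}

# ---- sensor stream rendering ------------------------------------------------

sim_app_table <- function() {
  data.table(
    app = sprintf("app%02d", 1:21),
    category = rep(APP_CATEGORIES, times = 3L)
  )
}

# contiguous missing spans for interval streams: a span-day drops a random
# 10-50% window of its ticks
apply_missing_spans <- function(dt, rate) {
  if (rate <= 0 || nrow(dt) == 0L) return(dt)
  dt[, "tick_idx" := seq_len(.N), by = c("participant_id", "date")]
  dt[, "n_tick" := .N, by = c("participant_id", "date")]
  days <- dt[, .(n_tick = data.table::first(n_tick)),
             by = c("participant_id", "date")]
  days[, "hit" := runif(.N) < rate]
  days[, "span_len" := pmax(1L, as.integer(floor(runif(.N, 0.1, 0.5) * days$n_tick)))]
  days[, "span_start" := 1L + as.integer(floor(runif(.N) *
                                                 (days$n_tick - days$span_len + 1L)))]
  dt <- days[, c("participant_id", "date", "hit", "span_start", "span_len"),
             with = FALSE][dt, on = c("participant_id", "date")]
  drop <- dt$hit & dt$tick_idx >= dt$span_start &
    dt$tick_idx < dt$span_start + dt$span_len
  dt <- dt[!drop]
  dt[, c("hit", "span_start", "span_len", "tick_idx", "n_tick") := NULL]
  dt
}

interval_ticks <- function(latent_days, interval_min) {
  ticks <- seq(0, 24 * 60 - interval_min, by = interval_min) * 60
  n <- nrow(latent_days)
  dt <- latent_days[rep(seq_len(n), each = length(ticks)),
                    c("participant_id", "date"), with = FALSE]
  dt[, "timestamp" := as.POSIXct(paste(dt$date, "00:00:00"), tz = "") +
       rep(ticks, times = n)]
  dt
}

render_gps <- function(latent, config, truth) {
  pd <- latent[, c("participant_id", "date"), with = FALSE]
  pd[, "mean_i" := rowMeans(as.matrix(latent[, item_cols_i(), with = FALSE]))]
  parts <- unique(pd$participant_id)
  anchors <- data.table(participant_id = parts)
  anchors[, "home_lat" := 37.50 + rnorm(.N, 0, 0.05)]
  anchors[, "home_lon" := 127.00 + rnorm(.N, 0, 0.05)]
  ang <- runif(nrow(anchors), 0, 2 * pi)
  r <- runif(nrow(anchors), 0.015, 0.05)
  anchors[, "work_lat" := anchors$home_lat + r * sin(ang)]
  anchors[, "work_lon" := anchors$home_lon + r * cos(ang)]
  ang2 <- runif(nrow(anchors), 0, 2 * pi)
  r2 <- runif(nrow(anchors), 0.008, 0.02)
  anchors[, "other_lat" := anchors$home_lat + r2 * sin(ang2)]
  anchors[, "other_lon" := anchors$home_lon + r2 * cos(ang2)]

  # day-level mobility decisions: a per-participant routine intercept
  # (commuters vs home-workers) dampened by symptom load
  anchors[, "mobility_b0" := rnorm(.N, 0, 1.2)]
  pd <- anchors[pd, on = "participant_id"]
  pd[, "weekday" := !format(pd$date, "%u") %in% c("6", "7")]
  p_leave <- stats::plogis(2.2 + pd$mobility_b0 - 1.2 * pd$mean_i)
  pd[, "go_work" := pd$weekday & runif(.N) < p_leave]
  pd[, "go_out" := !pd$weekday & runif(.N) < 0.7 * p_leave]

  dt <- interval_ticks(pd, 15)
  dt <- pd[dt, on = c("participant_id", "date")]
  hour <- as.numeric(format(dt$timestamp, "%H")) +
    as.numeric(format(dt$timestamp, "%M")) / 60
  place <- rep("home", nrow(dt))
  place[dt$go_work & hour >= 9 & hour < 18] <- "work"
  place[dt$go_out & hour >= 13 & hour < 16.5] <- "other"
  dt[, "lat" := data.table::fifelse(place == "home", dt$home_lat,
                data.table::fifelse(place == "work", dt$work_lat, dt$other_lat)) +
       rnorm(.N, 0, 1e-4)]
  dt[, "lon" := data.table::fifelse(place == "home", dt$home_lon,
                data.table::fifelse(place == "work", dt$work_lon, dt$other_lon)) +
       rnorm(.N, 0, 1e-4)]
  dt <- dt[, c("participant_id", "date", "timestamp", "lat", "lon"), with = FALSE]
  dt <- apply_missing_spans(dt, config$sensor_missing_rate)
  # planted outliers: displaced far from every cluster
  out <- runif(nrow(dt)) < config$sensor_outlier_rate
  if (any(out)) {
    n_out <- sum(out)
    dt$lat[out] <- dt$lat[out] + sample(c(-1, 1), n_out, TRUE) * runif(n_out, 0.05, 0.5)
    dt$lon[out] <- dt$lon[out] + sample(c(-1, 1), n_out, TRUE) * runif(n_out, 0.05, 0.5)
  }
  dt[, "source" := "gps"]
  dt[, "field" := "location"]
  dt[, "value" := NA_real_]
  dt[, "tag" := NA_character_]
  dt[, "planted_outlier" := out]
  dt
}

item_cols_i <- function() paste0("i", 1:9)

render_interval_values <- function(latent, config, source, interval_min) {
  dt <- interval_ticks(latent, interval_min)
  dt <- apply_missing_spans(dt, config$sensor_missing_rate)
  n <- nrow(dt)
  hour <- as.numeric(format(dt$timestamp, "%H"))
  daytime <- hour >= 7 & hour < 22
  emit <- function(field, value) {
    d <- data.table::copy(dt)
    d[, "field" := field]
    d[, "value" := value]
    d
  }
  rows <- switch(source,
    light = list(emit("lux", exp(rnorm(n, log(ifelse(daytime, 300, 5)), 0.6)))),
    gravity = list(emit("gravity_x", rnorm(n, 0.5, 1.0)),
                   emit("gravity_y", rnorm(n, 4.0, 1.0)),
                   emit("gravity_z", rnorm(n, 8.5, 1.0))),
    microphone = list(
      emit("energy", exp(rnorm(n, log(ifelse(daytime, 60, 5)), 0.8))),
      emit("pitch_detected", as.numeric(runif(n) < ifelse(daytime, 0.35, 0.05)))),
    wifi = list(emit("ap_count", as.numeric(rpois(n, 8)))),
    stored_media = list(emit("image_count", as.numeric(rpois(n, 120)))),
    stop_config("unknown interval source '%s'", source)
  )
  out <- data.table::rbindlist(rows)
  out[, "source" := source]
  out[, "tag" := NA_character_]
  out[]
}

render_event_source <- function(latent, config, source, rate_factor) {
  base <- EVENT_BASE_RATE[[source]]
  counts <- rpois(nrow(latent), base * rate_factor)
  idx <- rep(seq_len(nrow(latent)), times = counts)
  if (length(idx) == 0L) return(NULL)
  ev <- latent[idx, c("participant_id", "date"), with = FALSE]
  ev[, "timestamp" := as.POSIXct(paste(ev$date, "00:00:00"), tz = "") +
       runif(.N, 0, 86399)]
  n <- nrow(ev)
  apps <- sim_app_table()
  pick_apps <- function(k) apps$app[sample.int(nrow(apps), k, replace = TRUE)]
  rows <- switch(source,
    call_log = {
      dir <- sample(c("missed", "incoming", "outgoing"), n, TRUE,
                    prob = c(0.15, 0.45, 0.40))
      d <- data.table::copy(ev)
      d[, "field" := "duration_s"]
      d[, "value" := data.table::fifelse(dir == "missed", 0,
                                         rlnorm(n, log(120), 0.8))]
      d[, "tag" := dir]
      list(d)
    },
    app_usage = {
      app <- pick_apps(n)
      cat_ <- apps$category[match(app, apps$app)]
      d <- data.table::copy(ev)
      d[, "field" := "duration_s"]
      d[, "value" := rlnorm(n, log(300), 1.0)]
      d[, "tag" := paste(app, cat_, sep = "|")]
      list(d)
    },
    keystroke = {
      app <- pick_apps(n)
      cat_ <- apps$category[match(app, apps$app)]
      tag <- paste(app, cat_, sep = "|")
      mk <- function(field, value) {
        d <- data.table::copy(ev)
        d[, "field" := field]
        d[, "value" := value]
        d[, "tag" := tag]
        d
      }
      list(mk("presses", as.numeric(rpois(n, 40))),
           mk("backspaces", as.numeric(rpois(n, 5))),
           mk("autocorrections", as.numeric(rpois(n, 3))),
           mk("duration_s", rlnorm(n, log(45), 0.6)))
    },
    notifications = {
      app <- pick_apps(n)
      clicked <- runif(n) < 0.5
      d <- data.table::copy(ev)
      d[, "field" := "event"]
      d[, "value" := 1]
      d[, "tag" := app]
      dc <- ev[clicked]
      dc[, "field" := "decision_time_s"]
      dc[, "value" := rlnorm(.N, log(30), 0.9)]
      dc[, "tag" := app[clicked]]
      list(d, dc)
    },
    pedometer = {
      d <- data.table::copy(ev)
      d[, "field" := "steps"]
      d[, "value" := as.numeric(rpois(n, 400))]
      d[, "tag" := NA_character_]
      list(d)
    },
    physical_activity = {
      act <- sample(c(ACTIVITY_ACTIVE, ACTIVITY_INACTIVE), n, TRUE,
                    prob = c(0.25, 0.05, 0.05, 0.50, 0.15))
      d <- data.table::copy(ev)
      d[, "field" := "duration_s"]
      d[, "value" := rlnorm(n, log(1800), 0.7)]
      d[, "tag" := act]
      list(d)
    },
    screen = {
      d <- data.table::copy(ev)
      d[, "field" := "duration_s"]
      d[, "value" := rlnorm(n, log(180), 1.0)]
      d[, "tag" := NA_character_]
      list(d)
    },
    microphone = {
      d <- data.table::copy(ev)
      d[, "field" := "energy"]
      d[, "value" := exp(rnorm(n, log(60), 0.8))]
      d[, "tag" := NA_character_]
      dp <- data.table::copy(ev)
      dp[, "field" := "pitch_detected"]
      dp[, "value" := as.numeric(runif(n) < 0.3)]
      dp[, "tag" := NA_character_]
      list(d, dp)
    },
    stop_config("unknown event source '%s'", source)
  )
  out <- data.table::rbindlist(rows)
  out[, "source" := source]
  out[]
}

#' Render sensor streams from latent symptom states
#'
#' Interval sources are emitted at their registry cadence with missing spans
#' at the configured rate; event sources are emitted as Poisson events whose
#' daily rate is `base * exp(loading' intensities)`, a monotone function of
#' the loading-weighted latent intensities. A planted fraction of duration
#' records is negative and a planted fraction of GPS points is displaced far
#' from every mobility cluster.
#'
#' @param latent latent-state table from the simulator.
#' @param config a `sim_config`.
#' @return list with `sensors` (long record table) and `truth` (planted
#'   `gps_outliers` / `negative_durations` record ids).
#' @export
render_sensor_streams <- function(latent, config) {
  latent <- as_dt(latent, "latent")
  reg <- source_registry(config$platform)
  L <- config$symptom_sensor_loading_matrix
  I <- as.matrix(latent[, item_cols_i(), with = FALSE])
  # per participant-day log rate factors, kept in a sane band; intensities
  # saturate at the configured cap (behavioural floor effect)
  C <- pmin(I, config$symptom_effect_cap) %*% L
  C <- pmin(pmax(C, -3), 3)
  # device/lifestyle heterogeneity: per participant x event source base-rate
  # multipliers, independent of the latent state
  parts <- unique(latent$participant_id)
  ev_sources <- reg$source[reg$cadence == "event"]
  base_mult <- matrix(rlnorm(length(parts) * length(ev_sources),
                             0, config$participant_rate_sd),
                      nrow = length(parts),
                      dimnames = list(parts, ev_sources))

  blocks <- list()
  for (k in seq_len(nrow(reg))) {
    src <- reg$source[k]
    if (reg$cadence[k] == "interval") {
      if (src == "gps") {
        blocks[[length(blocks) + 1L]] <- render_gps(latent, config)
      } else {
        blocks[[length(blocks) + 1L]] <-
          render_interval_values(latent, config, src, reg$interval_min[k])
      }
    } else {
      blocks[[length(blocks) + 1L]] <- render_event_source(
        latent, config, src,
        exp(C[, src]) * base_mult[match(latent$participant_id, parts), src])
    }
  }
  sensors <- data.table::rbindlist(blocks, use.names = TRUE, fill = TRUE)
  if (!"lat" %in% names(sensors)) sensors[, "lat" := NA_real_]
  if (!"lon" %in% names(sensors)) sensors[, "lon" := NA_real_]
  if (!"planted_outlier" %in% names(sensors)) sensors[, "planted_outlier" := FALSE]
  sensors[is.na(sensors$planted_outlier), "planted_outlier" := FALSE]
  data.table::setorderv(sensors, c("participant_id", "source", "timestamp", "field"))
  sensors[, "record_id" := seq_len(.N)]

  # plant negative durations to exercise range cleaning
  is_dur <- sensors$field == "duration_s" & !is.na(sensors$value) &
    sensors$value > 0
  neg <- is_dur & runif(nrow(sensors)) < config$sensor_outlier_rate
  sensors[neg, "value" := -abs(sensors$value[neg])]

  truth <- list(
    gps_outliers = sensors$record_id[sensors$planted_outlier],
    negative_durations = sensors$record_id[neg]
  )
  sensors[, "planted_outlier" := NULL]
  keep <- c("record_id", "participant_id", "source", "timestamp", "field",
            "value", "tag", "lat", "lon")
  list(sensors = sensors[, keep, with = FALSE], truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Draws demographics, latent nine-dimensional symptom trajectories, EMA
#' responses and sensor streams as one deterministic function of the
#' configuration. Ground-truth severity labels per participant-day are the
#' latent totals bucketed with the same cutoffs the EMA pipeline uses, so
#' end-to-end recovery is well defined.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return object of class `cohort_bundle`: list with `config`,
#'   `demographics`, `latent`, `ema`, `sensors` and `truth` (planted
#'   artefacts plus daily latent severity labels).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_config("config must be built with simulation_config()")
  }
  with_seed(config$seed, {
    demographics <- simulate_demographics(config)
    latent <- simulate_latent(config, demographics)
    ema <- render_ema_responses(latent, config)
    sens <- render_sensor_streams(latent, config)
    severity_daily <- latent[, c("participant_id", "day", "date"), with = FALSE]
    severity_daily[, "latent_total" := rowSums(as.matrix(
      latent[, item_cols_i(), with = FALSE]))]
    severity_daily[, "severity" := classify_severity(severity_daily$latent_total)]
    structure(list(
      config = config,
      demographics = demographics,
      latent = latent,
      ema = ema$ema,
      sensors = sens$sensors,
      truth = c(ema$truth, sens$truth, list(severity_daily = severity_daily[]))
    ), class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants x %d days (%s), seed %d\n",
              x$config$n_participants, x$config$n_days, x$config$platform,
              x$config$seed))
  cat(sprintf("  EMA responses : %d\n", nrow(x$ema)))
  cat(sprintf("  sensor records: %d (%d sources)\n", nrow(x$sensors),
              length(unique(x$sensors$source))))
  cat(sprintf("  planted: %d trap errors, %d speeders, %d GPS outliers, %d negative durations\n",
              length(x$truth$trap_errors), length(x$truth$speeders),
              length(x$truth$gps_outliers), length(x$truth$negative_durations)))
  invisible(x)
}

#' Planted-signal scenario configuration for recovery experiments
#'
#' Builds a simulation configuration in which two designated "driver"
#' symptoms dominate the cohort: they carry most of the day-to-day latent
#' variance (hence the item-total correlation) and load strongly on several
#' event sources, so both the self-reports and the sensor streams are
#' driven by the same two symptoms. Used by the end-to-end recovery
#' experiments.
#'
#' @param n_participants,n_days cohort size.
#' @param seed integer seed.
#' @param drivers indices of the two driver symptoms (default 1-2:
#'   diminished interest and depressed mood).
#' @param platform `"android"` or `"ios"`.
#' @return a `sim_config`.
#' @export
recovery_scenario_config <- function(n_participants = 60L, n_days = 90L,
                                     seed = 1L, drivers = c(1L, 2L),
                                     platform = "android") {
  stopifnot(length(drivers) == 2L, all(drivers %in% 1:9))
  # single-factor latent structure: the drivers carry the common depression
  # factor almost purely (loading 1, little unique noise), the other items
  # follow it with more unique noise, so the two drivers dominate both the
  # totals and the item-total correlations
  loadings <- rep(0.8, 9L)
  loadings[drivers] <- 1.0
  unique_sd <- rep(0.40, 9L)
  unique_sd[drivers] <- 0.20
  intercepts <- rep(0.30, 9L)
  intercepts[drivers] <- 0
  sources <- unique(source_registry(platform)$source)
  L <- matrix(0, nrow = 9L, ncol = length(sources),
              dimnames = list(PHQ9_ITEMS, sources))
  couple <- function(j, source, value) {
    if (source %in% sources) L[j, source] <<- value
  }
  couple(drivers[1], "pedometer", -0.7)
  couple(drivers[1], "app_usage", -0.5)
  couple(drivers[1], "notifications", -0.4)
  couple(drivers[1], "physical_activity", -0.4)
  couple(drivers[2], "call_log", -0.6)
  couple(drivers[2], "screen", 0.5)
  couple(drivers[2], "keystroke", -0.4)
  couple(drivers[2], "microphone", -0.4)
  simulation_config(
    n_participants = n_participants, n_days = n_days, platform = platform,
    symptom_noise_sd = 0.18,
    group_means = c(0.30, 1.55, 2.70),
    factor_loadings = loadings, factor_unique_sd = unique_sd,
    item_intercepts = intercepts,
    symptom_effect_cap = 1.75,
    symptom_sensor_loading_matrix = L,
    seed = seed)
}
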