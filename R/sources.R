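# Registry of passive-sensing data sources and the daily feature schema.
#
# Sources are either interval-based (sampled on a fixed cadence) or
# event-based (emitted when something happens: a call, an unlock, a typing
# session). Each source belongs to one or more measurement categories --
# duration, value, quantity -- which determine the daily features extracted
# from it: duration/value sources yield mean and variance, quantity sources
# yield a cumulative count. Voluntary or low-variability sources (SNS, music,
# SMS, camera, calendar, significant motion) are excluded from analysis and
# never appear here.

#' Default application-category significance map
#'
#' App-usage and keystroke features distinguish "significant" from
#' "non-significant" applications. Which categories count as significant is
#' deployment-specific, so the map is an editable table; the default marks
#' social, work and study apps as significant.
#'
#' @return data.table with columns `category`, `significant`.
#' @export
app_significance_map <- function() {
  data.table(
    category = APP_CATEGORIES,
    significant = APP_CATEGORIES %in% c("social", "work", "study")
  )
}

#' Registry of analysed data sources
#'
#' One row per data source available on the given platform, with its cadence
#' kind, collection interval (interval sources only) and measurement
#' categories.
#'
#' @param platform `"android"` or `"ios"`.
#' @return data.table with columns `source`, `cadence` ("interval" or
#'   "event"), `interval_min` (minutes; `NA` for event sources) and
#'   `categories` (comma-separated subset of duration/value/quantity).
#' @export
source_registry <- function(platform = c("android", "ios")) {
  platform <- match.arg(platform)
  reg <- data.table::rbindlist(list(
    list("app_usage",         "android",     "event",    NA_real_, "duration"),
    list("call_log",          "android,ios", "event",    NA_real_, "duration,quantity"),
    list("gps",               "android,ios", "interval", 15,       "value"),
    list("gravity",           "android,ios", "interval", 15,       "value"),
    list("keystroke",         "android",     "event",    NA_real_, "duration,quantity"),
    list("light",             "android",     "interval", 15,       "value"),
    list("microphone",        "android",     "interval", 15,       "value,quantity"),
    list("microphone",        "ios",         "event",    NA_real_, "value,quantity"),
    list("notifications",     "android",     "event",    NA_real_, "value,quantity"),
    list("pedometer",         "android,ios", "event",    NA_real_, "quantity"),
    list("physical_activity", "android,ios", "event",    NA_real_, "duration"),
    list("screen",            "android,ios", "event",    NA_real_, "duration"),
    list("stored_media",      "android,ios", "interval", 240,      "value"),
    list("wifi",              "android",     "interval", 30,       "value")
  ))
  data.table::setnames(reg, c("source", "platform", "cadence", "interval_min",
                              "categories"))
  keep <- vapply(strsplit(reg$platform, ",", fixed = TRUE),
                 function(p) platform %in% p, logical(1L))
  reg <- reg[keep]
  reg[, "platform" := NULL]
  reg[]
}

#' Valid measurement ranges per source field
#'
#' Range cleaning removes records whose field value falls outside the
#' physically plausible interval for that source; durations and counts must
#' be non-negative, coordinates must be on the globe.
#'
#' @return data.table with columns `source`, `field`, `min`, `max`.
#' @export
field_ranges <- function() {
  rng <- data.table::rbindlist(list(
    list("app_usage",         "duration_s",      0, 86400),
    list("call_log",          "duration_s",      0, 86400),
    list("gps",               "lat",           -90, 90),
    list("gps",               "lon",          -180, 180),
    list("gravity",           "gravity_x",     -30, 30),
    list("gravity",           "gravity_y",     -30, 30),
    list("gravity",           "gravity_z",     -30, 30),
    list("keystroke",         "presses",         0, 1e5),
    list("keystroke",         "backspaces",      0, 1e5),
    list("keystroke",         "autocorrections", 0, 1e5),
    list("keystroke",         "duration_s",      0, 86400),
    list("light",             "lux",             0, 2e5),
    list("microphone",        "energy",          0, 1e6),
    list("microphone",        "pitch_detected",  0, 1),
    list("notifications",     "event",           0, 1),
    list("notifications",     "decision_time_s", 0, 86400),
    list("pedometer",         "steps",           0, 1e5),
    list("physical_activity", "duration_s",      0, 86400),
    list("screen",            "duration_s",      0, 86400),
    list("stored_media",      "image_count",     0, 1e6),
    list("wifi",              "ap_count",        0, 1000)
  ))
  data.table::setnames(rng, c("source", "field", "min", "max"))
  rng[]
}

#' Daily feature schema for a platform
#'
#' Enumerates every daily feature column extracted from the platform's source
#' set, before pruning: 68 columns for Android and 34 for iOS. Demographic
#' and calendar columns (day of week, gender, age group) are part of the
#' schema.
#'
#' @param platform `"android"` or `"ios"`.
#' @return data.table with columns `column`, `source`, `category`.
#' @export
feature_schema <- function(platform = c("android", "ios")) {
  platform <- match.arg(platform)
  rows <- list(
    list("day_of_week", "additional", "demographic"),
    list("gender",      "additional", "demographic"),
    list("age_group",   "additional", "demographic")
  )
  add <- function(column, source, category) {
    rows[[length(rows) + 1L]] <<- list(column, source, category)
  }
  sources <- source_registry(platform)$source
  if ("app_usage" %in% sources) {
    for (g in c(APP_CATEGORIES, "significant", "nonsignificant")) {
      add(sprintf("app_%s_duration_mean", g), "app_usage", "duration")
      add(sprintf("app_%s_duration_var", g), "app_usage", "duration")
    }
  }
  if ("call_log" %in% sources) {
    for (d in c("missed", "incoming", "outgoing")) {
      add(sprintf("calls_%s_n", d), "call_log", "quantity")
    }
    for (d in c("incoming", "outgoing")) {
      add(sprintf("calls_%s_duration_mean", d), "call_log", "duration")
      add(sprintf("calls_%s_duration_var", d), "call_log", "duration")
    }
  }
  if ("gps" %in% sources) {
    for (col in c("loc_time_home_h", "loc_time_work_h", "loc_time_other_h",
                  "loc_total_distance_km", "loc_max_home_distance_km",
                  "loc_visited_places_n", "loc_displacement_sd_km")) {
      add(col, "gps", "value")
    }
  }
  if ("gravity" %in% sources) {
    for (ax in c("x", "y", "z")) {
      add(sprintf("gravity_%s_mean", ax), "gravity", "value")
      add(sprintf("gravity_%s_var", ax), "gravity", "value")
    }
  }
  if ("keystroke" %in% sources) {
    add("keys_pressed_n", "keystroke", "quantity")
    add("keys_backspace_n", "keystroke", "quantity")
    add("keys_autocorrect_n", "keystroke", "quantity")
    add("keys_unique_apps_n", "keystroke", "quantity")
    for (g in c("sig", "nonsig")) {
      add(sprintf("typing_%s_duration_mean", g), "keystroke", "duration")
      add(sprintf("typing_%s_duration_var", g), "keystroke", "duration")
    }
  }
  if ("light" %in% sources) {
    add("light_mean", "light", "value")
    add("light_var", "light", "value")
  }
  if ("microphone" %in% sources) {
    add("sound_energy_mean", "microphone", "value")
    add("sound_energy_var", "microphone", "value")
    add("pitch_detected_n", "microphone", "quantity")
  }
  if ("notifications" %in% sources) {
    add("notif_arrived_n", "notifications", "quantity")
    add("notif_clicked_n", "notifications", "quantity")
    add("notif_unique_apps_n", "notifications", "quantity")
    add("notif_decision_time_mean", "notifications", "value")
    add("notif_decision_time_var", "notifications", "value")
  }
  if ("pedometer" %in% sources) add("steps_n", "pedometer", "quantity")
  if ("physical_activity" %in% sources) {
    for (g in c("active", "inactive")) {
      add(sprintf("activity_%s_duration_mean", g), "physical_activity", "duration")
      add(sprintf("activity_%s_duration_var", g), "physical_activity", "duration")
    }
  }
  if ("screen" %in% sources) {
    add("screen_unlocked_duration_mean", "screen", "duration")
    add("screen_unlocked_duration_var", "screen", "duration")
  }
  if ("stored_media" %in% sources) add("media_images_mean", "stored_media", "value")
  if ("wifi" %in% sources) add("wifi_ap_mean", "wifi", "value")

  out <- data.table::rbindlist(rows)
  data.table::setnames(out, c("column", "source", "category"))
  out[]
}
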