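# Shared fixtures: tiny hand-built logs and timeline objects.

`%||%` <- function(a, b) if (is.null(a)) b else a

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# a minimal classified log row set; `label` drives everything downstream
mini_log <- function(user_id, timestamp, label, pregnancy_week = NA_integer_,
                     age = NA_integer_) {
  tibble::tibble(
    user_id = user_id,
    timestamp = ts_utc(timestamp),
    text = paste0("synthetic ", label),
    age = as.integer(age),
    gender = "female",
    label = factor(label, levels = c(
      "missed_oc", "pregnancy_week", "emergency_contraception",
      "miscarriage", "abortion", "other"
    )),
    pregnancy_week = as.integer(pregnancy_week),
    n_missed_doses = NA_integer_,
    pill_combined = ifelse(label == "missed_oc", FALSE, NA),
    pill_progestin = ifelse(label == "missed_oc", FALSE, NA),
    placebo_mentioned = ifelse(label == "missed_oc", FALSE, NA),
    pill_type = factor(
      ifelse(label == "missed_oc", "unspecified", NA_character_),
      levels = c("combined", "progestin_only", "both", "unspecified")
    )
  )
}

# build an oc_timelines object directly from per-user ages and follow-up flags
make_timelines <- function(ages, followup_users, class = "miscarriage") {
  n <- length(ages)
  users <- tibble::tibble(
    user_id = sprintf("u%04d", seq_len(n)),
    index_ts = ts_utc("2018-03-01 12:00:00"),
    index_date = as.Date("2018-03-01"),
    age = as.integer(ages),
    gender = "female",
    n_missed_doses = NA_integer_,
    pill_combined = FALSE,
    pill_progestin = FALSE,
    placebo_mentioned = FALSE,
    pill_type = factor("unspecified",
      levels = c("combined", "progestin_only", "both", "unspecified")
    )
  )
  followups <- tibble::tibble(
    user_id = users$user_id[followup_users],
    label = class,
    ts = ts_utc("2018-03-10 12:00:00"),
    pregnancy_week = NA_integer_,
    gap_days = 9
  )
  structure(
    list(users = users, followups = followups, n_dropped = 0L),
    class = "oc_timelines"
  )
}

small_scenario <- function(n = 500, ...) {
  scenario_config(n_users = n, ...)
}
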