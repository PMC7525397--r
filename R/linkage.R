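#' Build per-user timelines anchored at the first missed-OC query
#'
#' Groups a classified log by user, anchors each timeline at the user's
#' first missed-OC query (the index date), and records the first follow-up
#' query of each class at or after the index. Users without a missed-OC
#' query are dropped (their count is reported). Ties in timestamp are
#' broken by stable input order.
#'
#' Conventions: "subsequent" means at or after the index timestamp
#' (same-day emergency-contraception queries are the clinically salient
#' case, so gap 0 counts), and only the first query of each class per user
#' enters the gap statistics.
#'
#' @param classified A log with classification columns, from
#'   [classify_queries()].
#' @return An object of class `oc_timelines`: a list with
#'   \describe{
#'     \item{users}{one row per cohort user: `user_id`, `index_ts`,
#'       `index_date`, demographics and first-missed-query attributes.}
#'     \item{followups}{first follow-up per user and class: `user_id`,
#'       `label`, `ts`, `gap_days` (fractional days since index).}
#'     \item{n_dropped}{users in the log with no missed-OC query.}
#'   }
#' @export
build_timelines <- function(classified) {
  cl <- as_tibble(classified)
  need <- c("user_id", "timestamp", "label")
  if (!all(need %in% names(cl))) {
    abort("`classified` must have user_id, timestamp and label columns; run classify_queries() first.")
  }
  ord <- order(cl$user_id, cl$timestamp)
  cl <- cl[ord, , drop = FALSE]

  is_idx <- cl$label == "missed_oc"
  idx <- cl[is_idx, , drop = FALSE]
  first <- !duplicated(idx$user_id)
  users <- tibble(
    user_id = idx$user_id[first],
    index_ts = idx$timestamp[first],
    index_date = as.Date(idx$timestamp[first], tz = "UTC"),
    age = idx$age[first],
    gender = idx$gender[first],
    n_missed_doses = idx$n_missed_doses[first],
    pill_combined = idx$pill_combined[first],
    pill_progestin = idx$pill_progestin[first],
    placebo_mentioned = idx$placebo_mentioned[first],
    pill_type = idx$pill_type[first]
  )
  n_dropped <- length(unique(cl$user_id)) - nrow(users)
  if (n_dropped > 0) {
    inform(sprintf("%d user(s) without a missed-OC query dropped.", n_dropped))
  }

  fu_classes <- c(
    "miscarriage", "abortion", "emergency_contraception", "pregnancy_week"
  )
  fu <- cl[cl$label %in% fu_classes, , drop = FALSE]
  fu <- fu[fu$user_id %in% users$user_id, , drop = FALSE]
  pos <- match(fu$user_id, users$user_id)
  keep <- fu$timestamp >= users$index_ts[pos]
  fu <- fu[keep, , drop = FALSE]
  firstfu <- !duplicated(paste(fu$user_id, fu$label))
  fu <- fu[firstfu, , drop = FALSE]
  pos <- match(fu$user_id, users$user_id)
  followups <- tibble(
    user_id = fu$user_id,
    label = as.character(fu$label),
    ts = fu$timestamp,
    pregnancy_week = fu$pregnancy_week,
    gap_days = as.numeric(difftime(fu$timestamp, users$index_ts[pos],
      units = "days"
    ))
  )
  structure(
    list(users = users, followups = followups, n_dropped = n_dropped),
    class = "oc_timelines"
  )
}

#' @export
print.oc_timelines <- function(x, ...) {
  cat(sprintf(
    "<oc_timelines> %d users with an index missed-OC query; %d first follow-ups\n",
    nrow(x$users), nrow(x$followups)
  ))
  invisible(x)
}

# median as the lower of the two middle order statistics on even counts
median_lower <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) return(NA_real_)
  x[ceiling(n / 2)]
}

#' Gap-time statistics for one follow-up class
#'
#' Gap = first follow-up timestamp of the class minus the index timestamp,
#' in fractional days. The median uses lower interpolation on even counts;
#' "within 24 hours" means a gap strictly below 1 day.
#'
#' @param timelines An [build_timelines()] object.
#' @param class One of `miscarriage`, `abortion`, `emergency_contraception`,
#'   `pregnancy_week`.
#' @return A list with `n`, `median_gap_days`, `fraction_within_24h`, and
#'   the `gaps` vector. An empty class yields `n = 0` with `NA` statistics,
#'   not an error.
#' @export
gap_stats <- function(timelines, class) {
  stopifnot(inherits(timelines, "oc_timelines"))
  g <- timelines$followups$gap_days[timelines$followups$label == class]
  if (length(g) == 0) {
    return(list(
      n = 0L, median_gap_days = NA_real_,
      fraction_within_24h = NA_real_, gaps = numeric(0)
    ))
  }
  list(
    n = length(g),
    median_gap_days = median_lower(g),
    fraction_within_24h = mean(g < 1),
    gaps = g
  )
}

#' Users whose class query precedes their first pregnancy-week query
#'
#' @inheritParams gap_stats
#' @return Count of users whose first query of `class` strictly precedes
#'   their first pregnancy-week query; users lacking either contribute 0.
#' @export
followed_by_pregnancy <- function(timelines, class) {
  stopifnot(inherits(timelines, "oc_timelines"))
  fu <- timelines$followups
  a <- fu[fu$label == class, c("user_id", "ts")]
  b <- fu[fu$label == "pregnancy_week", c("user_id", "ts")]
  m <- match(a$user_id, b$user_id)
  sum(!is.na(m) & a$ts < b$ts[m])
}

#' Follow-up incidence and gap-time summary per class
#'
#' @inheritParams gap_stats
#' @return A tibble with one row per follow-up class: user counts,
#'   fraction of missed-OC users, gap-time median and within-24h fraction,
#'   and the count whose class query precedes their first pregnancy-week
#'   query.
#' @export
followup_summary <- function(timelines) {
  stopifnot(inherits(timelines, "oc_timelines"))
  n_users <- nrow(timelines$users)
  classes <- c(
    "miscarriage", "abortion", "emergency_contraception", "pregnancy_week"
  )
  rows <- lapply(classes, function(cls) {
    gs <- gap_stats(timelines, cls)
    tibble(
      class = cls,
      n_users_with_followup = gs$n,
      fraction_of_missed_users = if (n_users > 0) gs$n / n_users else NA_real_,
      median_gap_days = gs$median_gap_days,
      fraction_within_24h = gs$fraction_within_24h,
      n_before_pregnancy = followed_by_pregnancy(timelines, cls)
    )
  })
  dplyr::bind_rows(rows)
}
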