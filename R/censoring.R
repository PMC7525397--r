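#' Empirical week-of-pregnancy query distribution
#'
#' The probability that a pregnancy-week query mentions gestational week k,
#' estimated as the fraction of all pregnancy-week queries in the log that
#' report week k. All pregnancy-week queries are used (not only those of
#' missed-OC users), maximising the sample behind the censoring weights.
#'
#' @param classified A classified log ([classify_queries()]), or an integer
#'   vector of reported weeks.
#' @return An object of class `oc_week_dist`: a tibble (`week`, `p`) with
#'   an `n_queries` attribute.
#' @export
estimate_week_distribution <- function(classified) {
  weeks <- if (is.numeric(classified)) {
    as.integer(classified)
  } else {
    cl <- as_tibble(classified)
    as.integer(cl$pregnancy_week[cl$label == "pregnancy_week"])
  }
  weeks <- weeks[!is.na(weeks) & weeks >= 1L & weeks <= 45L]
  if (length(weeks) == 0) {
    abort(paste0(
      "No pregnancy-week queries in the input; censoring weights cannot be ",
      "estimated. Supply a configured prior week distribution instead."
    ))
  }
  tab <- tabulate(weeks, nbins = 45L)
  keep <- tab > 0L
  out <- tibble(week = which(keep), p = tab[keep] / sum(tab))
  attr(out, "n_queries") <- length(weeks)
  class(out) <- c("oc_week_dist", class(out))
  out
}

#' Observability weight of a missed-OC user
#'
#' The probability that a pregnancy following the index date would produce
#' an observable pregnancy-week query inside the window:
#' `w = sum_k p(k) * 1[index_date + 7 k <= window_end]`. A user whose full
#' support of weeks is observable gets weight 1; weights are non-increasing
#' in the index date. When used as a denominator contribution the weight is
#' clipped below at `floor` so that a single very late index date cannot
#' dominate the estimator.
#'
#' @param index_date Date vector of index missed-OC dates.
#' @param dist An [estimate_week_distribution()] object.
#' @param window_end Last date of the observation window.
#' @param weight_floor Lower clip for the weight (default 0.01); use `0`
#'   for the raw weight.
#' @return Numeric vector of weights in `(0, 1]` (or `[0, 1]` when
#'   `floor = 0`).
#' @export
compute_weight <- function(index_date, dist, window_end, weight_floor = 0.01) {
  stopifnot(inherits(dist, "oc_week_dist"))
  window_end <- as.Date(window_end)
  kstar <- as.integer(floor(
    as.numeric(window_end - as.Date(index_date)) / 7
  ))
  cum <- c(0, cumsum(dist$p))
  # weight = P(week <= kstar) under the empirical distribution
  idx <- findInterval(kstar, dist$week) + 1L
  w <- cum[pmax(idx, 1L)]
  w[kstar < 0L] <- 0
  pmax(w, weight_floor)
}

#' Censoring-corrected pregnancy rate
#'
#' Horvitz-Thompson-style estimator applied to the denominator only: the
#' count of observed pregnancies divided by the effective
#' (observable-equivalent) cohort size `sum_i w_i`. An observed pregnancy
#' counts 1 in the numerator regardless of its weight. A fully-weighted
#' variant (pregnancies divided by their own weight as well) is available
#' for sensitivity analysis via `both_sides = TRUE`.
#'
#' @param weights Numeric vector of user weights in `(0, 1]`.
#' @param pregnant Logical/0-1 vector: user observed pregnant (issued a
#'   pregnancy-week query after the index).
#' @param both_sides Also weight the numerator (sensitivity variant).
#' @return List: `weighted`, `unweighted`, `n_users`, `n_pregnant`,
#'   `effective_n`.
#' @export
#' @examples
#' weighted_pregnancy_rate(c(1, 0.5, 0.5), c(TRUE, FALSE, FALSE))
weighted_pregnancy_rate <- function(weights, pregnant, both_sides = FALSE) {
  stopifnot(length(weights) == length(pregnant))
  if (length(weights) == 0) {
    return(list(
      weighted = NA_real_, unweighted = NA_real_,
      n_users = 0L, n_pregnant = 0L, effective_n = 0
    ))
  }
  if (any(weights <= 0 | weights > 1)) {
    abort("weights must lie in (0, 1]; apply the floor before calling.")
  }
  pregnant <- as.logical(pregnant)
  num <- if (both_sides) sum(1 / weights[pregnant]) else sum(pregnant)
  list(
    weighted = num / sum(weights),
    unweighted = mean(pregnant),
    n_users = length(weights),
    n_pregnant = sum(pregnant),
    effective_n = sum(weights)
  )
}

#' Weighted pregnancy rates by subgroup
#'
#' Applies [weighted_pregnancy_rate()] within strata defined by the
#' missed-OC query attributes.
#'
#' @param users A per-user tibble with columns `weight`, `pregnant` and the
#'   attribute columns `pill_combined`, `pill_progestin`,
#'   `placebo_mentioned`, `n_missed_doses` (see [cohort_user_table()]).
#' @param grouping One of `"pill_type"` (strata: combined mention,
#'   progestin/minipill mention, no type mentioned -- overlapping strata,
#'   a user mentioning both types contributes to both), `"placebo"`, or
#'   `"dose_count_2plus"`.
#' @param min_stratum Strata below this size are flagged `small = TRUE`.
#' @return A tibble: stratum, n_users, n_pregnant, effective_n, weighted
#'   and unweighted rates, small-stratum flag.
#' @export
subgroup_rates <- function(users, grouping, min_stratum = 50L) {
  need <- c(
    "weight", "pregnant", "pill_combined", "pill_progestin",
    "placebo_mentioned", "n_missed_doses"
  )
  if (!all(need %in% names(users))) {
    abort("`users` must be a cohort user table (see cohort_user_table()).")
  }
  strata <- switch(grouping,
    pill_type = list(
      combined = users$pill_combined %in% TRUE,
      progestin_only = users$pill_progestin %in% TRUE,
      unspecified = !(users$pill_combined %in% TRUE) &
        !(users$pill_progestin %in% TRUE)
    ),
    placebo = list(
      placebo = users$placebo_mentioned %in% TRUE,
      non_placebo = !(users$placebo_mentioned %in% TRUE)
    ),
    dose_count_2plus = list(
      two_plus = !is.na(users$n_missed_doses) & users$n_missed_doses >= 2L,
      fewer_or_unstated = is.na(users$n_missed_doses) |
        users$n_missed_doses < 2L
    ),
    abort(paste0("Unknown grouping: ", grouping))
  )
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    r <- weighted_pregnancy_rate(users$weight[sel], users$pregnant[sel])
    tibble(
      stratum = nm, n_users = r$n_users, n_pregnant = r$n_pregnant,
      effective_n = r$effective_n, weighted_rate = r$weighted,
      unweighted_rate = r$unweighted, small = r$n_users < min_stratum
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-user cohort table with weights and observed-pregnancy indicator
#'
#' Joins the timeline users with their censoring weight and whether they
#' were observed pregnant (issued at least one pregnancy-week query at or
#' after the index date).
#'
#' @param timelines An [build_timelines()] object.
#' @param dist An [estimate_week_distribution()] object.
#' @param window_end Last date of the observation window.
#' @param weight_floor Weight floor passed to [compute_weight()].
#' @return The `timelines$users` tibble with `weight` and `pregnant`
#'   columns added.
#' @export
cohort_user_table <- function(timelines, dist, window_end, weight_floor = 0.01) {
  stopifnot(inherits(timelines, "oc_timelines"))
  users <- timelines$users
  users$weight <- compute_weight(users$index_date, dist, window_end, weight_floor)
  preg_users <- unique(
    timelines$followups$user_id[timelines$followups$label == "pregnancy_week"]
  )
  users$pregnant <- users$user_id %in% preg_users
  users
}

#' Percentile bootstrap for the weighted rate
#'
#' Resamples users with replacement and recomputes the weighted rate.
#'
#' @inheritParams weighted_pregnancy_rate
#' @param n_boot Number of bootstrap replicates.
#' @param conf Confidence level.
#' @return List: `estimate`, `lower`, `upper`, `n_boot`.
#' @export
bootstrap_rate_ci <- function(weights, pregnant, n_boot = 200L, conf = 0.95) {
  n <- length(weights)
  est <- weighted_pregnancy_rate(weights, pregnant)$weighted
  reps <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n, n, replace = TRUE)
    sum(pregnant[j]) / sum(weights[j])
  }, 0)
  a <- (1 - conf) / 2
  list(
    estimate = est,
    lower = unname(quantile(reps, a)),
    upper = unname(quantile(reps, 1 - a)),
    n_boot = n_boot
  )
}
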