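#' Infer the first day of the last menstrual period
#'
#' LMP is dated by subtracting the reported gestational weeks from the
#' query date: `LMP = query_date - 7 * week`.
#'
#' @param query_date Date (or coercible) of the pregnancy-week query.
#' @param week Reported gestational week, integer in 1--45.
#' @return Date vector.
#' @export
#' @examples
#' infer_lmp(as.Date("2018-06-15"), 10) # 2018-04-06
infer_lmp <- function(query_date, week) {
  week <- as.integer(week)
  if (any(!is.na(week) & (week < 1L | week > 45L))) {
    abort("`week` must be in [1, 45]; filter out-of-range weeks upstream.")
  }
  as.Date(query_date) - 7L * week
}

#' Consistency of recurrent LMP inferences
#'
#' The median over all unordered pairs of absolute day differences between
#' the per-query inferred LMP dates of one user. Permutation-invariant in
#' the query list.
#'
#' @param lmps Date (or numeric day) vector of inferred LMPs for one user.
#' @return Median pairwise absolute difference in days; `NA` with fewer
#'   than two queries.
#' @export
#' @examples
#' d <- as.Date("2018-03-01")
#' lmp_consistency(c(d, d + 2, d + 6)) # pairs {2, 6, 4} -> 4
lmp_consistency <- function(lmps) {
  x <- as.numeric(lmps)
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  dd <- abs(outer(x, x, "-"))
  median(dd[upper.tri(dd)])
}

#' Classify a pregnancy as timed to the missed-pill cycle
#'
#' A pregnancy is timed when the index missed-OC date falls inside the
#' conception cycle, i.e. `0 <= index_date - consensus_LMP < cycle_length`.
#' For timed pregnancies the offset of the index date from the consensus
#' LMP is returned as the conception-day estimate (the missed-dose date as
#' the proxy exposure day within the cycle).
#'
#' @param consensus_lmp Consensus inferred LMP date(s).
#' @param index_date Index missed-OC date(s).
#' @param cycle_length Cycle length in days (default 28).
#' @return A list with logical `timed` and integer `conception_day`
#'   (`NA` when untimed).
#' @export
classify_timed <- function(consensus_lmp, index_date, cycle_length = 28L) {
  off <- as.numeric(as.Date(index_date) - as.Date(consensus_lmp))
  timed <- !is.na(off) & off >= 0 & off < cycle_length
  list(
    timed = timed,
    conception_day = ifelse(timed, as.integer(off), NA_integer_)
  )
}

#' Infer pregnancies from pregnancy-week follow-up queries
#'
#' For every cohort user with an index missed-OC query and at least one
#' pregnancy-week query at or after the index, infers a per-query LMP,
#' forms the consensus LMP (the lower median of the per-query dates),
#' scores the consistency of recurrent inferences, and classifies the
#' pregnancy as timed to the index cycle.
#'
#' @param timelines An [build_timelines()] object.
#' @param classified The classified log the timelines were built from (all
#'   pregnancy-week queries of the cohort users are used, not only the
#'   first).
#' @param cycle_length Cycle length in days.
#' @return A tibble: `user_id`, `n_queries`, `consensus_lmp`,
#'   `consistency_days` (`NA` for single-query users), `timed`,
#'   `conception_day`.
#' @export
infer_pregnancies <- function(timelines, classified, cycle_length = 28L) {
  stopifnot(inherits(timelines, "oc_timelines"))
  cl <- as_tibble(classified)
  pw <- cl[cl$label == "pregnancy_week" & !is.na(cl$pregnancy_week), ,
    drop = FALSE
  ]
  pos <- match(pw$user_id, timelines$users$user_id)
  keep <- !is.na(pos) & pw$timestamp >= timelines$users$index_ts[pos]
  pw <- pw[keep, , drop = FALSE]
  if (nrow(pw) == 0) {
    return(tibble(
      user_id = character(0), n_queries = integer(0),
      consensus_lmp = as.Date(character(0)), consistency_days = numeric(0),
      timed = logical(0), conception_day = integer(0)
    ))
  }
  lmp <- infer_lmp(as.Date(pw$timestamp, tz = "UTC"), pw$pregnancy_week)
  sp <- split(as.numeric(lmp), pw$user_id)
  user_id <- names(sp)
  n_queries <- lengths(sp)
  consensus <- as.Date(
    unname(vapply(sp, function(x) sort(x)[ceiling(length(x) / 2)], 0)),
    origin = "1970-01-01"
  )
  consistency <- unname(vapply(sp, lmp_consistency, 0))
  idx <- timelines$users$index_date[match(user_id, timelines$users$user_id)]
  ct <- classify_timed(consensus, idx, cycle_length)
  tibble(
    user_id = user_id,
    n_queries = as.integer(n_queries),
    consensus_lmp = consensus,
    consistency_days = consistency,
    timed = ct$timed,
    conception_day = ct$conception_day
  )
}
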