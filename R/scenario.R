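#' Scenario configuration for the synthetic query-log generator
#'
#' Builds and validates the parameter set that [generate_cohort()] draws
#' from. Defaults encode the study conditions the analysis is designed for:
#' a one-calendar-year observation window (2018), the published dose-count
#' and pill-type mention distributions, subgroup pregnancy rates, gap-time
#' summaries, conception-day distribution, the 19% timed fraction, the
#' 4-day LMP-consistency target and the age-band follow-up ratios.
#'
#' Several generator parameters are derived, not free:
#' \itemize{
#'   \item Per-user pregnancy probabilities are assigned by mutually
#'     exclusive risk class (placebo mention; progestin-only mention;
#'     >=2 missed doses; remainder) and the two free class probabilities are
#'     solved so that the marginal rates of the placebo, minipill, 2+-dose
#'     and overall non-placebo strata equal the configured targets.
#'   \item Gap-time distributions are a two-part mixture: a sub-24h uniform
#'     component with the configured within-day mass, plus a log-normal
#'     whose median is solved so the overall median equals the configured
#'     class median. (A single log-normal cannot carry both summaries
#'     without placing a third of its mass beyond the window.)
#'   \item The age distribution is a two-component normal mixture solved
#'     from the configured mean/SD/mode.
#' }
#'
#' @param n_users Number of cohort users (each issues one missed-OC query).
#' @param n_background Number of background users issuing only
#'   pregnancy-week queries; they stabilise the empirical week-of-pregnancy
#'   distribution used by the censoring weights. Default `2 * n_users`.
#' @param window_start,window_end Observation window (dates).
#' @param age_mean,age_sd,age_mode Targets for the age distribution.
#' @param age_missing_prob Fraction of users with unreported age.
#' @param dose_count_pmf Probabilities over dose-count mentions
#'   (unspecified, 1, 2, 3, 4+). Must sum to 1.
#' @param pill_mention_probs Marginal mention probabilities
#'   (none, combined, progestin); combined + progestin may overlap, with
#'   overlap mass implied by `1 - none`.
#' @param placebo_fraction Fraction of cohort users mentioning a placebo
#'   pill (drawn among users with no brand mention and <2 stated doses).
#' @param rate_nonplacebo,rate_minipill,rate_placebo,rate_two_plus Target
#'   per-cycle pregnancy rates of the corresponding strata.
#' @param followup_probs Baseline probabilities that a cohort user later
#'   issues a miscarriage / abortion / emergency-contraception query.
#' @param age_multipliers Relative-risk multipliers applied inside one age
#'   band per class (band vs complement ratio targets).
#' @param gap_params Per-class gap-time summaries: median (days) and
#'   within-24h mass.
#' @param gap_sigma Log-normal sigma of the beyond-24h gap component.
#' @param conception_mean,conception_sd Truncated-normal conception-day
#'   offset (days after cycle start), truncated to `[0, cycle_length)`.
#' @param cycle_length Menstrual cycle length in days.
#' @param timed_fraction Fraction of pregnancies conceived in the cycle of
#'   the missed-OC query.
#' @param week_pmf_peak,week_pmf_range Triangular pmf of the anchor
#'   gestational week of pregnancy queries (mode and support).
#' @param n_query_pmf Probabilities of 1, 2 or 3 pregnancy-week queries per
#'   pregnant user.
#' @param date_jitter,week_error_zero Reporting-noise parameters: query
#'   dates scatter uniformly within `date_jitter` days of the anchor
#'   gestational day, and the reported week equals the true week with
#'   probability `week_error_zero` (else +/-1). Jointly calibrated so the
#'   cohort median pairwise difference between inferred LMPs is 4 days.
#' @param untimed_cycles,untimed_lmp_nudge Placement of pregnancies not
#'   timed to the index cycle: conception `untimed_cycles` cycles before the
#'   index cycle, with a small day nudge per cycle choice balancing the
#'   observability of their (further-along) pregnancy queries.
#' @param other_query_prob Probability a cohort user also issues one
#'   unrelated ("other") query.
#' @param index_start,index_end Range of missed-OC query dates (defaults to
#'   the full window; an uncensored scenario uses an early sub-range).
#' @return An object of class `oc_scenario` (a validated named list with
#'   derived fields `risk_classes`, `gap_mixture`, `age_mixture`,
#'   `placebo_cond_prob`, `week_pmf`, `preg_mult_norm`).
#' @export
#' @examples
#' cfg <- scenario_config(n_users = 500)
#' cfg$risk_classes
scenario_config <- function(
    n_users = 50000,
    n_background = NULL,
    window_start = as.Date("2018-01-01"),
    window_end = as.Date("2018-12-31"),
    age_mean = 32, age_sd = 12, age_mode = 20,
    age_missing_prob = 0.10,
    dose_count_pmf = c(
      unspecified = 0.671, `1` = 0.214, `2` = 0.063,
      `3` = 0.034, `4+` = 0.018
    ),
    pill_mention_probs = c(none = 0.608, combined = 0.209, progestin = 0.217),
    placebo_fraction = 0.10,
    rate_nonplacebo = 0.047,
    rate_minipill = 0.087,
    rate_placebo = 0.002,
    rate_two_plus = 0.051,
    followup_probs = c(
      miscarriage = 0.03, abortion = 0.05,
      emergency_contraception = 0.10
    ),
    age_multipliers = list(
      abortion = list(band = "under30", mult = 1.5),
      emergency_contraception = list(band = "under30", mult = 1.7),
      pregnancy = list(band = "30-34", mult = 2.1),
      miscarriage = list(band = "30-34", mult = 5.4)
    ),
    gap_params = list(
      emergency_contraception = list(median = 11, p_within_day = 0.37),
      abortion = list(median = 28, p_within_day = 0.20),
      miscarriage = list(median = 35, p_within_day = 0.07)
    ),
    gap_sigma = 0.45,
    conception_mean = 14.4, conception_sd = 7.2,
    cycle_length = 28L,
    timed_fraction = 0.19,
    week_pmf_peak = 8L, week_pmf_range = c(4L, 24L),
    n_query_pmf = c(`1` = 0.45, `2` = 0.35, `3` = 0.20),
    date_jitter = 3L,
    week_error_zero = 0.695,
    untimed_cycles = c(1L, 2L),
    untimed_lmp_nudge = c(0L, 14L),
    other_query_prob = 0.30,
    index_start = NULL,
    index_end = NULL) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (!(window_start < window_end)) {
    abort("`window_start` must precede `window_end`.")
  }
  if (is.null(n_background)) n_background <- 2L * as.integer(n_users)
  if (is.null(index_start)) index_start <- window_start
  if (is.null(index_end)) index_end <- window_end
  index_start <- as.Date(index_start)
  index_end <- as.Date(index_end)

  bad <- character(0)
  check_pmf <- function(p, nm) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) bad <<- c(bad, nm)
  }
  check_pmf(dose_count_pmf, "dose_count_pmf")
  check_pmf(n_query_pmf, "n_query_pmf")
  rates <- c(
    rate_nonplacebo, rate_minipill, rate_placebo, rate_two_plus,
    placebo_fraction, timed_fraction, age_missing_prob, other_query_prob,
    followup_probs
  )
  if (any(rates < 0 | rates > 1)) bad <- c(bad, "a rate outside [0, 1]")
  if (n_users < 0) bad <- c(bad, "n_users")
  for (g in gap_params) {
    if (g$median <= 0 || g$p_within_day < 0 || g$p_within_day >= 1) {
      bad <- c(bad, "gap_params")
    }
  }
  if (length(bad) > 0) {
    abort(paste0(
      "Invalid scenario configuration: ",
      paste(unique(bad), collapse = ", ")
    ))
  }

  cfg <- list(
    n_users = as.integer(n_users), n_background = as.integer(n_background),
    window_start = window_start, window_end = window_end,
    age_mean = age_mean, age_sd = age_sd, age_mode = age_mode,
    age_missing_prob = age_missing_prob,
    dose_count_pmf = dose_count_pmf,
    pill_mention_probs = pill_mention_probs,
    placebo_fraction = placebo_fraction,
    rate_nonplacebo = rate_nonplacebo, rate_minipill = rate_minipill,
    rate_placebo = rate_placebo, rate_two_plus = rate_two_plus,
    followup_probs = followup_probs,
    age_multipliers = age_multipliers,
    gap_params = gap_params, gap_sigma = gap_sigma,
    conception_mean = conception_mean, conception_sd = conception_sd,
    cycle_length = as.integer(cycle_length),
    timed_fraction = timed_fraction,
    week_pmf_peak = as.integer(week_pmf_peak),
    week_pmf_range = as.integer(week_pmf_range),
    n_query_pmf = n_query_pmf,
    date_jitter = as.integer(date_jitter),
    week_error_zero = week_error_zero,
    untimed_cycles = as.integer(untimed_cycles),
    untimed_lmp_nudge = as.integer(untimed_lmp_nudge),
    other_query_prob = other_query_prob,
    index_start = index_start, index_end = index_end
  )

  cfg$age_mixture <- solve_age_mixture(age_mean, age_sd, age_mode)
  cfg$week_pmf <- triangular_week_pmf(week_pmf_range, week_pmf_peak)
  cfg$gap_mixture <- lapply(gap_params, function(g) {
    solve_gap_mixture(g$median, g$p_within_day, gap_sigma)
  })
  cfg$pill_joint <- solve_pill_joint(pill_mention_probs)
  cfg$placebo_cond_prob <- solve_placebo_cond(cfg)
  cfg$risk_classes <- solve_risk_classes(cfg)
  cfg$preg_mult_norm <- pregnancy_mult_norm(cfg)
  structure(cfg, class = "oc_scenario")
}

# two-component normal mixture matching mean/sd/mode: a narrow young
# component pinned at the mode plus a broad older component.
solve_age_mixture <- function(mean, sd, mode, young_weight = 0.35,
                              young_sd = 3) {
  older_mean <- (mean - young_weight * mode) / (1 - young_weight)
  m2 <- sd^2 + mean^2
  older_var <- (m2 - young_weight * (young_sd^2 + mode^2)) / (1 - young_weight) -
    older_mean^2
  if (older_var <= 0) abort("Age mixture targets are infeasible.")
  list(
    young_weight = young_weight, young_mean = mode, young_sd = young_sd,
    older_mean = older_mean, older_sd = sqrt(older_var)
  )
}

triangular_week_pmf <- function(range, peak) {
  wk <- seq(range[1], range[2])
  p <- ifelse(wk <= peak, wk - range[1] + 1,
    (peak - range[1] + 1) * (range[2] - wk) / (range[2] - peak)
  )
  tibble(week = as.integer(wk), p = p / sum(p))
}

# mixture: with prob p1, gap ~ U(0, 1) day; else log-normal with sigma and
# median m2 solved so that the overall median equals `med`.
solve_gap_mixture <- function(med, p1, sigma) {
  stopifnot(p1 < 0.5)
  z <- qnorm((0.5 - p1) / (1 - p1))
  list(p_within_day = p1, meanlog = log(med) - z * sigma, sdlog = sigma)
}

# joint pill-mention classes from marginals with overlap implied by `none`
solve_pill_joint <- function(p) {
  both <- p[["combined"]] + p[["progestin"]] - (1 - p[["none"]])
  if (both < 0) abort("pill_mention_probs imply negative overlap.")
  out <- c(
    none = p[["none"]],
    combined_only = p[["combined"]] - both,
    progestin_only = p[["progestin"]] - both,
    both = both
  )
  if (any(out < 0) || abs(sum(out) - 1) > 1e-9) {
    abort("pill_mention_probs are inconsistent.")
  }
  out
}

# placebo mentions are drawn among users with no brand mention and fewer
# than two stated doses; the conditional probability reproduces the overall
# placebo fraction.
solve_placebo_cond <- function(cfg) {
  eligible <- cfg$pill_joint[["none"]] *
    (cfg$dose_count_pmf[["unspecified"]] + cfg$dose_count_pmf[["1"]])
  cond <- cfg$placebo_fraction / eligible
  if (cond > 1) abort("placebo_fraction exceeds the eligible user mass.")
  cond
}

# Mutually exclusive pregnancy-risk classes with precedence
# placebo > progestin mention > 2+ doses > base. The 2+ (non-progestin) and
# base probabilities are solved so the *marginal* rates of the measured
# strata (2+ doses; all non-placebo users) hit their targets.
solve_risk_classes <- function(cfg) {
  p_prog <- cfg$pill_mention_probs[["progestin"]]
  p_2p <- sum(cfg$dose_count_pmf[c("2", "3", "4+")])
  m_placebo <- cfg$placebo_fraction
  m_prog <- p_prog
  m_2p_nonprog <- (1 - p_prog) * p_2p
  m_base <- 1 - m_placebo - m_prog - m_2p_nonprog
  # 2+ stratum: progestin users with 2+ doses at the minipill rate, rest q2
  q2 <- (p_2p * cfg$rate_two_plus - p_prog * p_2p * cfg$rate_minipill) /
    m_2p_nonprog
  # non-placebo stratum at rate_nonplacebo
  q3 <- ((1 - m_placebo) * cfg$rate_nonplacebo -
    m_prog * cfg$rate_minipill - m_2p_nonprog * q2) / m_base
  if (q2 <= 0 || q2 >= 1 || q3 <= 0 || q3 >= 1) {
    abort("Stratum rate targets are jointly infeasible.")
  }
  tibble(
    class = c("placebo", "progestin", "two_plus", "base"),
    mass = c(m_placebo, m_prog, m_2p_nonprog, m_base),
    rate = c(cfg$rate_placebo, cfg$rate_minipill, q2, q3)
  )
}

# normalisation of the 30-34 pregnancy multiplier so stratum rate targets
# stay marginal over age
pregnancy_mult_norm <- function(cfg) {
  mix <- cfg$age_mixture
  p_band <- function(lo, hi) {
    mix$young_weight *
      (pnorm(hi, mix$young_mean, mix$young_sd) -
        pnorm(lo, mix$young_mean, mix$young_sd)) +
      (1 - mix$young_weight) *
        (pnorm(hi, mix$older_mean, mix$older_sd) -
          pnorm(lo, mix$older_mean, mix$older_sd))
  }
  p3034 <- p_band(29.5, 34.5)
  mult <- cfg$age_multipliers$pregnancy$mult
  list(p_band = p3034, norm = 1 + (mult - 1) * p3034)
}

#' @export
print.oc_scenario <- function(x, ...) {
  cat("<oc_scenario>\n")
  cat(sprintf(
    "  %d cohort users (+%d background), window %s .. %s\n",
    x$n_users, x$n_background,
    format(x$window_start), format(x$window_end)
  ))
  cat(sprintf(
    "  pregnancy rates: non-placebo %.3f, minipill %.3f, placebo %.3f, 2+ doses %.3f\n",
    x$rate_nonplacebo, x$rate_minipill, x$rate_placebo, x$rate_two_plus
  ))
  cat(sprintf(
    "  timed fraction %.2f, conception offset %.1f (SD %.1f) d\n",
    x$timed_fraction, x$conception_mean, x$conception_sd
  ))
  invisible(x)
}
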