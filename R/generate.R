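#' Generate a synthetic query log with ground truth
#'
#' Draws a per-user query log with the statistical structure the analysis
#' pipeline assumes, plus a per-user ground-truth sidecar, so that every
#' downstream estimator can be validated by parameter recovery.
#'
#' Each cohort user issues exactly one missed-OC query at a date uniform in
#' the index window, with text synthesised from unambiguous class templates
#' (so that [classify_queries()] recovers the intended label and
#' attributes). Follow-up miscarriage / abortion / emergency-contraception
#' queries are emitted at the index time plus a gap drawn from the class
#' gap-time mixture, only while inside the window. Pregnant users receive a
#' true LMP (the cycle start of the conception cycle) and issue
#' pregnancy-week queries whose dates are anchored at the reported
#' gestational day; queries dated after the window end are silently lost --
#' the right-censoring mechanism the observability weights undo. Background
#' users issue only pregnancy-week queries, with LMPs spread uniformly over
#' an interval wide enough that their observed reported-week distribution is
#' an unbiased estimate of the configured week pmf.
#'
#' @param config An [scenario_config()] object.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A list with elements `log` (tibble: user_id, timestamp, text,
#'   age, gender) sorted by timestamp, and `truth` (one row per cohort
#'   user; see [write_truth()]).
#' @export
#' @examples
#' sim <- generate_cohort(scenario_config(n_users = 200), seed = 1)
#' head(sim$log)
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "oc_scenario"))
  set.seed(as.integer(seed))
  n <- config$n_users
  if (n == 0L) {
    return(list(log = empty_log(), truth = empty_truth()))
  }

  day0 <- config$window_start
  idx_days <- as.integer(config$index_end - config$index_start)
  index_date <- config$index_start +
    sample.int(idx_days + 1L, n, replace = TRUE) - 1L
  index_ts <- as.POSIXct(index_date, tz = "UTC") +
    round(runif(n, 0, 86399))

  ## demographics ------------------------------------------------------
  mix <- config$age_mixture
  young <- runif(n) < mix$young_weight
  age_cont <- ifelse(young,
    rnorm(n, mix$young_mean, mix$young_sd),
    rnorm(n, mix$older_mean, mix$older_sd)
  )
  age <- pmin(pmax(round(age_cont), 13L), 80L)
  age_known <- runif(n) >= config$age_missing_prob
  gender <- ifelse(runif(n) < 0.97, "female", "unknown")
  band <- age_band(age)

  ## dose count, weakly correlated with age (Gaussian copula) ----------
  z_age <- qnorm(pmin(pmax(age_mixture_cdf(age_cont, mix), 1e-12), 1 - 1e-12))
  rho <- 0.12
  z_dose <- rho * z_age + sqrt(1 - rho^2) * rnorm(n)
  cuts <- cumsum(config$dose_count_pmf)
  dose_cat <- cut(pnorm(z_dose),
    breaks = c(0, cuts), labels = names(config$dose_count_pmf),
    include.lowest = TRUE
  )
  dose_cat <- as.character(dose_cat)
  n_doses <- rep(NA_integer_, n)
  n_doses[dose_cat == "1"] <- 1L
  n_doses[dose_cat == "2"] <- 2L
  n_doses[dose_cat == "3"] <- 3L
  n_doses[dose_cat == "4+"] <- sample(4:6, sum(dose_cat == "4+"), replace = TRUE)

  ## pill mentions and placebo -----------------------------------------
  pill_class <- sample(names(config$pill_joint), n,
    replace = TRUE, prob = config$pill_joint
  )
  eligible <- pill_class == "none" & dose_cat %in% c("unspecified", "1")
  placebo <- eligible & runif(n) < config$placebo_cond_prob

  ## pregnancy risk class (precedence) and probability ------------------
  rc <- config$risk_classes
  risk <- ifelse(placebo, "placebo",
    ifelse(pill_class %in% c("progestin_only", "both"), "progestin",
      ifelse(dose_cat %in% c("2", "3", "4+"), "two_plus", "base")
    )
  )
  base_rate <- rc$rate[match(risk, rc$class)]
  mult <- ifelse(band == config$age_multipliers$pregnancy$band,
    config$age_multipliers$pregnancy$mult, 1
  )
  p_preg <- base_rate * mult / config$preg_mult_norm$norm
  pregnant <- runif(n) < p_preg

  ## pregnancy mechanism ------------------------------------------------
  np <- sum(pregnant)
  preg <- pregnancy_draws(config, np)
  lmp <- conception <- rep(as.Date(NA), n)
  timed_true <- rep(NA, n)
  n_emitted <- rep(0L, n)
  preg_rows <- NULL
  if (np > 0) {
    idxp <- index_date[pregnant]
    nudge <- config$untimed_lmp_nudge[match(preg$cycles, config$untimed_cycles)]
    lmp_p <- idxp - preg$offset -
      ifelse(preg$timed, 0L, config$cycle_length * preg$cycles - nudge)
    conception_p <- lmp_p + preg$offset
    kk <- preg$week + ifelse(preg$timed, 0L, preg$week_shift)
    uid <- rep(which(pregnant), preg$m)
    jrep <- function(v) rep(v, preg$m)
    kq <- rep(kk, preg$m)
    tq <- sample(seq(-config$date_jitter, config$date_jitter),
      sum(preg$m),
      replace = TRUE
    )
    w0 <- config$week_error_zero
    Wq <- sample(c(-1L, 0L, 1L), sum(preg$m),
      replace = TRUE, prob = c((1 - w0) / 2, w0, (1 - w0) / 2)
    )
    d <- jrep(lmp_p) + 7L * kq + tq
    w_rep <- pmax(1L, pmin(45L, kq + Wq))
    keep <- d >= config$window_start & d <= config$window_end
    if (any(keep)) {
      preg_rows <- tibble(
        user = uid[keep],
        date = as.Date(d[keep], origin = "1970-01-01"),
        week = w_rep[keep]
      )
      cnt <- table(preg_rows$user)
      n_emitted[as.integer(names(cnt))] <- as.integer(cnt)
    }
    lmp[pregnant] <- lmp_p
    conception[pregnant] <- conception_p
    timed_true[pregnant] <- preg$timed
  }

  ## follow-up classes --------------------------------------------------
  fu_rows <- list()
  fu_true <- list()
  for (cls in names(config$followup_probs)) {
    am <- config$age_multipliers[[cls]]
    p_cls <- config$followup_probs[[cls]] *
      ifelse(in_band(band, am$band), am$mult, 1)
    has <- runif(n) < p_cls
    fu_true[[cls]] <- has
    k <- sum(has)
    if (k > 0) {
      gm <- config$gap_mixture[[cls]]
      gap <- draw_gaps(k, gm)
      ts <- index_ts[has] + gap * 86400
      keep <- as.Date(ts, tz = "UTC") <= config$window_end
      fu_rows[[cls]] <- tibble(
        user = which(has)[keep], ts = ts[keep], class = cls
      )
    }
  }

  ## other (noise) queries ----------------------------------------------
  has_other <- runif(n) < config$other_query_prob
  n_other <- sum(has_other)

  ## background pregnancy-week users ------------------------------------
  nb <- config$n_background
  bg_rows <- NULL
  if (nb > 0) {
    span <- as.integer(config$window_end - config$window_start)
    lmp_b <- config$window_start - 287L +
      sample.int(span + 288L, nb, replace = TRUE) - 1L
    kb <- sample(config$week_pmf$week, nb,
      replace = TRUE, prob = config$week_pmf$p
    )
    mb <- sample(as.integer(names(config$n_query_pmf)), nb,
      replace = TRUE, prob = config$n_query_pmf
    )
    uidb <- rep(seq_len(nb), mb)
    tb <- sample(seq(-config$date_jitter, config$date_jitter),
      sum(mb),
      replace = TRUE
    )
    w0 <- config$week_error_zero
    Wb <- sample(c(-1L, 0L, 1L), sum(mb),
      replace = TRUE, prob = c((1 - w0) / 2, w0, (1 - w0) / 2)
    )
    db <- rep(lmp_b, mb) + 7L * rep(kb, mb) + tb
    wb <- pmax(1L, pmin(45L, rep(kb, mb) + Wb))
    keep <- db >= config$window_start & db <= config$window_end
    if (any(keep)) {
      bg_rows <- tibble(
        user = uidb[keep],
        date = as.Date(db[keep], origin = "1970-01-01"),
        week = wb[keep]
      )
    }
  }

  ## synthesise text and assemble the log --------------------------------
  uid_str <- sprintf("u%06d", seq_len(n))
  missed_txt <- missed_query_text(config, dose_cat, n_doses, pill_class, placebo)

  logs <- list(tibble(
    user_id = uid_str, timestamp = index_ts, text = missed_txt,
    age = ifelse(age_known, age, NA_integer_), gender = gender
  ))
  for (cls in names(fu_rows)) {
    fr <- fu_rows[[cls]]
    if (is.null(fr) || nrow(fr) == 0) next
    logs[[length(logs) + 1L]] <- tibble(
      user_id = uid_str[fr$user], timestamp = fr$ts,
      text = followup_query_text(cls, nrow(fr)),
      age = ifelse(age_known[fr$user], age[fr$user], NA_integer_),
      gender = gender[fr$user]
    )
  }
  if (!is.null(preg_rows) && nrow(preg_rows) > 0) {
    ts <- as.POSIXct(preg_rows$date, tz = "UTC") +
      round(runif(nrow(preg_rows), 0, 86399))
    logs[[length(logs) + 1L]] <- tibble(
      user_id = uid_str[preg_rows$user], timestamp = ts,
      text = pregnancy_query_text(preg_rows$week),
      age = ifelse(age_known[preg_rows$user], age[preg_rows$user], NA_integer_),
      gender = gender[preg_rows$user]
    )
  }
  if (n_other > 0) {
    span <- as.integer(config$window_end - config$window_start)
    od <- config$window_start + sample.int(span + 1L, n_other, replace = TRUE) - 1L
    logs[[length(logs) + 1L]] <- tibble(
      user_id = uid_str[has_other],
      timestamp = as.POSIXct(od, tz = "UTC") + round(runif(n_other, 0, 86399)),
      text = other_query_text(n_other),
      age = ifelse(age_known[has_other], age[has_other], NA_integer_),
      gender = gender[has_other]
    )
  }
  if (!is.null(bg_rows) && nrow(bg_rows) > 0) {
    ts <- as.POSIXct(bg_rows$date, tz = "UTC") +
      round(runif(nrow(bg_rows), 0, 86399))
    bg_age <- pmin(pmax(round(rnorm(nrow(bg_rows), 29, 6)), 16L), 45L)
    logs[[length(logs) + 1L]] <- tibble(
      user_id = sprintf("b%06d", bg_rows$user), timestamp = ts,
      text = pregnancy_query_text(bg_rows$week),
      age = bg_age, gender = "female"
    )
  }
  log <- dplyr::bind_rows(logs)
  log <- log[order(log$timestamp), , drop = FALSE]

  truth <- tibble(
    user_id = uid_str,
    index_date = index_date,
    age = age,
    age_known = age_known,
    age_band = band,
    dose_category = dose_cat,
    pill_mention = pill_class,
    placebo = placebo,
    risk_class = risk,
    p_pregnancy = p_preg,
    pregnant = pregnant,
    timed = timed_true,
    lmp = lmp,
    conception_date = conception,
    n_preg_queries_emitted = n_emitted,
    censored = pregnant & n_emitted == 0L,
    followup_miscarriage = fu_true$miscarriage,
    followup_abortion = fu_true$abortion,
    followup_ec = fu_true$emergency_contraception
  )
  attr(truth, "scenario_targets") <- scenario_targets(config)
  attr(truth, "seed") <- as.integer(seed)
  list(log = as_tibble(log), truth = truth)
}

# per-pregnant-user draws: timed flag, conception offset, untimed cycle
# displacement, anchor gestational week, number of queries
pregnancy_draws <- function(config, np) {
  if (np == 0) {
    return(list(
      timed = logical(0), offset = integer(0), cycles = integer(0),
      week = integer(0), week_shift = integer(0), m = integer(0)
    ))
  }
  timed <- runif(np) < config$timed_fraction
  offset <- round(rtrunc_norm(
    np, config$conception_mean, config$conception_sd,
    0, config$cycle_length
  ))
  offset <- pmin(as.integer(offset), config$cycle_length - 1L)
  cycles <- sample(config$untimed_cycles, np, replace = TRUE)
  week <- sample(config$week_pmf$week, np,
    replace = TRUE, prob = config$week_pmf$p
  )
  week_shift <- as.integer(round(
    (config$cycle_length * cycles + config$conception_mean) / 7
  ))
  m <- sample(as.integer(names(config$n_query_pmf)), np,
    replace = TRUE, prob = config$n_query_pmf
  )
  list(
    timed = timed, offset = offset, cycles = cycles,
    week = week, week_shift = week_shift, m = m
  )
}

rtrunc_norm <- function(n, mu, sd, lo, hi) {
  u <- runif(n)
  plo <- pnorm(lo, mu, sd)
  phi <- pnorm(hi, mu, sd)
  qnorm(plo + u * (phi - plo), mu, sd)
}

draw_gaps <- function(k, gm) {
  within <- runif(k) < gm$p_within_day
  out <- numeric(k)
  out[within] <- runif(sum(within))
  out[!within] <- rlnorm(sum(!within), gm$meanlog, gm$sdlog)
  out
}

age_mixture_cdf <- function(x, mix) {
  mix$young_weight * pnorm(x, mix$young_mean, mix$young_sd) +
    (1 - mix$young_weight) * pnorm(x, mix$older_mean, mix$older_sd)
}

#' Age bands used in the age-stratified analyses
#'
#' @param age Integer vector of ages (years); `NA` allowed.
#' @return Factor with levels `<20`, `20-24`, `25-29`, `30-34`, `35-39`,
#'   `40+`.
#' @export
age_band <- function(age) {
  cut(age,
    breaks = c(-Inf, 19, 24, 29, 34, 39, Inf),
    labels = c("<20", "20-24", "25-29", "30-34", "35-39", "40+")
  )
}

in_band <- function(band, spec) {
  if (identical(spec, "under30")) {
    band %in% c("<20", "20-24", "25-29")
  } else {
    band == spec
  }
}

scenario_targets <- function(config) {
  list(
    rate_nonplacebo = config$rate_nonplacebo,
    rate_minipill = config$rate_minipill,
    rate_placebo = config$rate_placebo,
    rate_two_plus = config$rate_two_plus,
    timed_fraction = config$timed_fraction,
    conception_mean = config$conception_mean,
    lmp_consistency = 4,
    gap_medians = vapply(config$gap_params, function(g) g$median, 0),
    gap_within_day = vapply(config$gap_params, function(g) g$p_within_day, 0),
    age_ratio_miscarriage = config$age_multipliers$miscarriage$mult,
    n_users = config$n_users
  )
}

empty_log <- function() {
  tibble(
    user_id = character(0),
    timestamp = as.POSIXct(character(0), tz = "UTC"),
    text = character(0), age = integer(0), gender = character(0)
  )
}

empty_truth <- function() {
  tibble(
    user_id = character(0), index_date = as.Date(character(0)),
    age = integer(0), age_known = logical(0),
    age_band = factor(character(0)), dose_category = character(0),
    pill_mention = character(0), placebo = logical(0),
    risk_class = character(0), p_pregnancy = numeric(0),
    pregnant = logical(0), timed = logical(0),
    lmp = as.Date(character(0)), conception_date = as.Date(character(0)),
    n_preg_queries_emitted = integer(0), censored = logical(0),
    followup_miscarriage = logical(0), followup_abortion = logical(0),
    followup_ec = logical(0)
  )
}
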