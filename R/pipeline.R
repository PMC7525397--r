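#' Run the full analysis pipeline on a query log
#'
#' Classify -> link -> gestation -> censoring -> cohort statistics, with
#' every reported number recomputable from the input log and options.
#'
#' @param log A query-log tibble (`user_id`, `timestamp`, `text`, optional
#'   `age`, `gender`), e.g. from [generate_cohort()] or [read_query_log()].
#' @param lexicon An [oc_lexicon()] list.
#' @param window_start,window_end Observation window; records outside it
#'   are counted and excluded.
#' @param cycle_length Menstrual cycle length for the timed-pregnancy
#'   classification.
#' @param weight_floor Lower clip for censoring weights.
#' @param min_stratum Minimum subgroup size before flagging.
#' @return An object of class `oc_report` (a nested list): run metadata,
#'   classification counts, follow-up summary, week distribution, overall
#'   and subgroup weighted/unweighted pregnancy rates, gestation statistics
#'   (timed fraction, conception-day mean/SD, LMP consistency), age-band
#'   comparisons and the age-dose correlation.
#' @export
#' @examples
#' sim <- generate_cohort(scenario_config(n_users = 300), seed = 7)
#' rep <- analyze_cohort(sim$log)
#' rep$rates$overall$weighted
analyze_cohort <- function(log,
                           lexicon = oc_lexicon(),
                           window_start = as.Date("2018-01-01"),
                           window_end = as.Date("2018-12-31"),
                           cycle_length = 28L,
                           weight_floor = 0.01,
                           min_stratum = 50L) {
  log <- as_tibble(log)
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)

  n_input <- nrow(log)
  empty_txt <- is.na(log$text) | trimws(log$text) == ""
  dates <- as.Date(log$timestamp, tz = "UTC")
  out_of_window <- !empty_txt & (dates < window_start | dates > window_end)
  keep <- !empty_txt & !out_of_window
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf(
      "Excluded %d record(s): %d empty text, %d outside %s..%s.",
      n_skipped, sum(empty_txt), sum(out_of_window),
      format(window_start), format(window_end)
    ))
  }
  log <- log[keep, , drop = FALSE]

  classified <- classify_queries(log, lexicon)
  class_counts <- as.list(table(classified$label))

  timelines <- build_timelines(classified)
  fu_summary <- followup_summary(timelines)

  have_pw <- any(classified$label == "pregnancy_week")
  if (nrow(timelines$users) > 0 && have_pw) {
    dist <- estimate_week_distribution(classified)
    users <- cohort_user_table(timelines, dist, window_end, weight_floor)
    overall <- weighted_pregnancy_rate(users$weight, users$pregnant)
    nonplacebo <- subgroup_rates(users, "placebo", min_stratum)
    rates <- list(
      overall = overall,
      placebo = nonplacebo,
      pill_type = subgroup_rates(users, "pill_type", min_stratum),
      dose_count_2plus = subgroup_rates(users, "dose_count_2plus", min_stratum)
    )
    preg <- infer_pregnancies(timelines, classified, cycle_length)
    gestation <- list(
      n_reporters = nrow(preg),
      timed_fraction = if (nrow(preg) > 0) mean(preg$timed) else NA_real_,
      n_timed = sum(preg$timed),
      conception_day_mean = if (any(preg$timed)) {
        mean(preg$conception_day[preg$timed])
      } else {
        NA_real_
      },
      conception_day_sd = if (sum(preg$timed) > 1) {
        sd(preg$conception_day[preg$timed])
      } else {
        NA_real_
      },
      n_recurrent = sum(preg$n_queries >= 2L),
      lmp_consistency_median = if (any(preg$n_queries >= 2L)) {
        median(preg$consistency_days[preg$n_queries >= 2L])
      } else {
        NA_real_
      }
    )
  } else {
    dist <- NULL
    users <- if (nrow(timelines$users) > 0) {
      u <- timelines$users
      u$weight <- rep(1, nrow(u))
      u$pregnant <- rep(FALSE, nrow(u))
      u
    } else {
      NULL
    }
    rates <- list(
      overall = weighted_pregnancy_rate(numeric(0), logical(0)),
      placebo = NULL, pill_type = NULL, dose_count_2plus = NULL
    )
    preg <- NULL
    gestation <- list(
      n_reporters = 0L, timed_fraction = NA_real_, n_timed = 0L,
      conception_day_mean = NA_real_, conception_day_sd = NA_real_,
      n_recurrent = 0L, lmp_consistency_median = NA_real_
    )
  }

  age_stats <- if (nrow(timelines$users) > 0 &&
    any(!is.na(timelines$users$age))) {
    comparisons <- list(
      abortion = c("under30", "abortion"),
      emergency_contraception = c("under30", "emergency_contraception"),
      pregnancy_week = c("30-34", "pregnancy_week"),
      miscarriage = c("30-34", "miscarriage")
    )
    bc <- dplyr::bind_rows(lapply(comparisons, function(x) {
      tryCatch(age_band_ratio(timelines, x[2], band = x[1]),
        error = function(e) NULL
      )
    }))
    list(
      band_comparisons = bc,
      correlation = age_dose_correlation(
        timelines$users$age, timelines$users$n_missed_doses
      )
    )
  } else {
    list(band_comparisons = NULL, correlation = NULL)
  }

  tab <- if (nrow(timelines$users) > 0) tabulate_missed(timelines) else NULL

  report <- list(
    meta = list(
      n_records_input = n_input,
      n_records_excluded = n_skipped,
      high_skip_warning = n_input > 0 && n_skipped / n_input > 0.10,
      window = c(format(window_start), format(window_end)),
      cycle_length = cycle_length,
      weight_floor = weight_floor,
      log_hash = rlang::hash(log),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ),
    classification = class_counts,
    n_cohort_users = nrow(timelines$users),
    followups = fu_summary,
    week_distribution = dist,
    rates = rates,
    gestation = gestation,
    missed_tabulation = tab,
    age = age_stats,
    pregnancies = preg,
    users = users
  )
  class(report) <- "oc_report"
  report
}

#' @export
print.oc_report <- function(x, ...) {
  cat("<oc_report>\n")
  cat(sprintf(
    "  %d records -> %d cohort users\n",
    x$meta$n_records_input, x$n_cohort_users
  ))
  ov <- x$rates$overall
  if (!is.na(ov$weighted)) {
    cat(sprintf(
      "  pregnancy rate: weighted %.2f%% (unweighted %.2f%%), %d pregnant / %d users\n",
      100 * ov$weighted, 100 * ov$unweighted, ov$n_pregnant, ov$n_users
    ))
    cat(sprintf(
      "  timed %.1f%%, conception day %.1f (SD %.1f), LMP consistency %.1f d\n",
      100 * x$gestation$timed_fraction, x$gestation$conception_day_mean,
      x$gestation$conception_day_sd, x$gestation$lmp_consistency_median
    ))
  }
  invisible(x)
}

#' Write an analysis report as JSON (with TSV side tables)
#'
#' @param report An [analyze_cohort()] report.
#' @param path Output JSON path. Tabular sections (follow-up summary, week
#'   distribution, subgroup rates, age comparisons) are additionally
#'   written as TSV files next to it, sharing its basename.
#' @param tsv Write the TSV side tables (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, tsv = TRUE) {
  stopifnot(inherits(report, "oc_report"))
  out <- report
  out$users <- NULL # per-user table goes to TSV, not JSON
  out$pregnancies <- NULL
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    force = TRUE
  )
  if (tsv) {
    stem <- sub("\\.json$", "", path)
    wt <- function(df, suffix) {
      if (!is.null(df) && nrow(df) > 0) {
        write.table(as.data.frame(df), paste0(stem, "_", suffix, ".tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
      }
    }
    wt(report$followups, "followups")
    wt(report$week_distribution, "week_distribution")
    wt(report$rates$pill_type, "rates_pill_type")
    wt(report$rates$placebo, "rates_placebo")
    wt(report$rates$dose_count_2plus, "rates_dose2plus")
    wt(report$age$band_comparisons, "age_bands")
    wt(report$pregnancies, "pregnancies")
  }
  invisible(path)
}

#' Simulate a cohort to files
#'
#' Thin file-level wrapper over [scenario_config()] + [generate_cohort()].
#'
#' @param out_log,out_truth Output paths (TSV).
#' @param seed Integer seed.
#' @param config An `oc_scenario`, or a path to a YAML file of
#'   [scenario_config()] arguments, or `NULL` for defaults.
#' @param n_users Overrides the configured `n_users` when not `NULL`.
#' @return Invisibly, the list from [generate_cohort()].
#' @export
simulate_to_files <- function(out_log, out_truth, seed = 1L, config = NULL,
                              n_users = NULL) {
  cfg <- resolve_scenario(config, n_users)
  sim <- generate_cohort(cfg, seed = seed)
  write_query_log(sim$log, out_log)
  write_truth(sim$truth, out_truth)
  invisible(sim)
}

resolve_scenario <- function(config, n_users = NULL) {
  if (is.null(config)) {
    args <- list()
  } else if (inherits(config, "oc_scenario")) {
    if (!is.null(n_users)) {
      abort("Pass n_users through scenario_config() when supplying an oc_scenario.")
    }
    return(config)
  } else if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    args <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    args <- config
  } else {
    abort("`config` must be NULL, an oc_scenario, a list, or a YAML path.")
  }
  if (!is.null(n_users)) args$n_users <- n_users
  do.call(scenario_config, args)
}

#' Compare pipeline estimates against simulation ground truth
#'
#' Builds the parameter-recovery table the validation suite relies on:
#' for each target quantity, the generator's configured truth, the
#' pipeline's estimate, an approximate standard error, and the z-score.
#'
#' @param report An [analyze_cohort()] report produced from a simulated
#'   log.
#' @param truth The ground-truth sidecar from the same simulation (or its
#'   [read_truth()] round trip).
#' @return A tibble: quantity, truth, estimate, se, z.
#' @export
recover_report <- function(report, truth) {
  stopifnot(inherits(report, "oc_report"))
  tg <- attr(truth, "scenario_targets")
  if (is.null(tg)) {
    abort("`truth` carries no scenario_targets attribute; was it generated by generate_cohort()?")
  }
  if (report$n_cohort_users != nrow(truth)) {
    abort(sprintf(
      "Report covers %d cohort users but truth has %d rows; mismatched run?",
      report$n_cohort_users, nrow(truth)
    ))
  }
  if (!setequal(report$users$user_id, truth$user_id)) {
    abort("User ids in report and truth differ; mismatched run?")
  }
  m <- match(truth$user_id, report$users$user_id)
  if (any(truth$index_date != report$users$index_date[m])) {
    abort("Per-user index dates disagree between report and truth; mismatched or corrupted sidecar?")
  }
  rate_row <- function(tbl, stratum, quantity, tr) {
    r <- tbl[tbl$stratum == stratum, ]
    se <- sqrt(r$n_pregnant) / r$effective_n
    tibble(
      quantity = quantity, truth = tr, estimate = r$weighted_rate,
      se = se, z = (r$weighted_rate - tr) / se
    )
  }
  g <- report$gestation
  n_rep <- g$n_reporters
  se_timed <- sqrt(g$timed_fraction * (1 - g$timed_fraction) / max(n_rep, 1))
  se_conc <- g$conception_day_sd / sqrt(max(g$n_timed, 1))
  ec <- gap_stats_from_report(report, "emergency_contraception")
  se_ec24 <- sqrt(ec$fraction_within_24h * (1 - ec$fraction_within_24h) /
    max(ec$n, 1))
  dplyr::bind_rows(
    rate_row(
      report$rates$placebo, "non_placebo", "rate_nonplacebo",
      tg$rate_nonplacebo
    ),
    rate_row(
      report$rates$pill_type, "progestin_only", "rate_minipill",
      tg$rate_minipill
    ),
    rate_row(report$rates$placebo, "placebo", "rate_placebo", tg$rate_placebo),
    rate_row(
      report$rates$dose_count_2plus, "two_plus", "rate_two_plus",
      tg$rate_two_plus
    ),
    tibble(
      quantity = "timed_fraction", truth = tg$timed_fraction,
      estimate = g$timed_fraction, se = se_timed,
      z = (g$timed_fraction - tg$timed_fraction) / se_timed
    ),
    tibble(
      quantity = "conception_day_mean", truth = tg$conception_mean,
      estimate = g$conception_day_mean, se = se_conc,
      z = (g$conception_day_mean - tg$conception_mean) / se_conc
    ),
    tibble(
      quantity = "lmp_consistency_median",
      truth = tg$lmp_consistency,
      estimate = g$lmp_consistency_median, se = NA_real_, z = NA_real_
    ),
    tibble(
      quantity = "ec_gap_median",
      truth = tg[["gap_medians.emergency_contraception"]] %||%
        tg$gap_medians[["emergency_contraception"]],
      estimate = ec$median_gap_days, se = NA_real_, z = NA_real_
    ),
    tibble(
      quantity = "ec_within_24h",
      truth = tg[["gap_within_day.emergency_contraception"]] %||%
        tg$gap_within_day[["emergency_contraception"]],
      estimate = ec$fraction_within_24h, se = se_ec24,
      z = (ec$fraction_within_24h - (tg[["gap_within_day.emergency_contraception"]] %||%
        tg$gap_within_day[["emergency_contraception"]])) / se_ec24
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gap_stats_from_report <- function(report, class) {
  fu <- report$followups
  r <- fu[fu$class == class, ]
  list(
    n = r$n_users_with_followup,
    median_gap_days = r$median_gap_days,
    fraction_within_24h = r$fraction_within_24h
  )
}
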