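test_that("degenerate scenarios produce the forced outputs", {
  sim0 <- generate_cohort(scenario_config(n_users = 0, n_background = 0), seed = 1)
  expect_equal(nrow(sim0$log), 0L)
  expect_equal(nrow(sim0$truth), 0L)

  # pregnancy probabilities ~0 and no background -> no pregnancy-week queries
  cfg <- scenario_config(
    n_users = 300, n_background = 0,
    rate_nonplacebo = 1e-12, rate_minipill = 2e-12,
    rate_placebo = 1e-13, rate_two_plus = 1.5e-12
  )
  sim <- generate_cohort(cfg, seed = 3)
  cl <- classify_queries(sim$log)
  expect_equal(sum(cl$label == "pregnancy_week"), 0L)
  expect_false(any(sim$truth$pregnant))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- small_scenario(400)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$log, b$log)
  expect_identical(a$truth, b$truth)
  d <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$log$text, d$log$text))
})

test_that("invalid configurations are rejected with named fields", {
  expect_error(
    scenario_config(window_start = "2018-12-31", window_end = "2018-01-01"),
    "window_start"
  )
  expect_error(
    scenario_config(dose_count_pmf = c(
      unspecified = 0.5, `1` = 0.2, `2` = 0.2, `3` = 0.2, `4+` = 0.1
    )),
    "dose_count_pmf"
  )
  expect_error(scenario_config(timed_fraction = 1.4), "rate")
  expect_error(
    scenario_config(placebo_fraction = 0.9),
    "placebo_fraction"
  )
  # stratum targets that force a negative base rate
  expect_error(
    scenario_config(rate_nonplacebo = 0.001, rate_minipill = 0.5),
    "infeasible"
  )
})

test_that("classifier label counts match generator intents exactly", {
  cfg <- scenario_config(n_users = 4000)
  sim <- generate_cohort(cfg, seed = 42)
  cl <- classify_queries(sim$log)
  tl <- suppressMessages(build_timelines(cl))
  tr <- sim$truth

  # every cohort user is recovered with an index event
  expect_setequal(tl$users$user_id, tr$user_id)
  m <- match(tl$users$user_id, tr$user_id)
  expect_identical(tl$users$index_date, tr$index_date[m])

  # attributes agree row-for-row with generator intent
  expect_true(all(tl$users$placebo_mentioned == tr$placebo[m]))
  expect_true(all(
    tl$users$pill_progestin ==
      (tr$pill_mention[m] %in% c("progestin_only", "both"))
  ))
  expect_true(all(
    tl$users$pill_combined ==
      (tr$pill_mention[m] %in% c("combined_only", "both"))
  ))
  dose_est <- ifelse(is.na(tl$users$n_missed_doses), "unspecified",
    ifelse(tl$users$n_missed_doses >= 4L, "4+",
      as.character(tl$users$n_missed_doses)
    )
  )
  expect_true(all(dose_est == tr$dose_category[m]))

  # follow-up intents: every truth flag has a matching labelled query
  for (spec in list(
    c("followup_miscarriage", "miscarriage"),
    c("followup_abortion", "abortion"),
    c("followup_ec", "emergency_contraception")
  )) {
    flagged <- tr$user_id[tr[[spec[1]]]]
    labelled <- unique(cl$user_id[cl$label == spec[2]])
    # labelled is flagged minus window-censored follow-ups
    expect_true(all(labelled %in% flagged))
  }
})

test_that("generated dose counts follow the configured distribution", {
  cfg <- scenario_config(n_users = 20000)
  sim <- generate_cohort(cfg, seed = 5)
  obs <- table(factor(sim$truth$dose_category,
    levels = names(cfg$dose_count_pmf)
  ))
  gof <- suppressWarnings(
    stats::chisq.test(as.numeric(obs), p = cfg$dose_count_pmf)
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("pregnancy observability decays with index month (the censoring signal)", {
  cfg <- scenario_config(n_users = 20000)
  sim <- generate_cohort(cfg, seed = 9)
  tr <- sim$truth[sim$truth$pregnant, ]
  month <- as.integer(format(tr$index_date, "%m"))
  emitted <- tr$n_preg_queries_emitted > 0
  early <- mean(emitted[month <= 3])
  late <- mean(emitted[month >= 10])
  expect_gt(early, 0.95)
  expect_lt(late, early - 0.3)
  # and the trend is monotone-ish: correlation of month with emission
  expect_lt(suppressWarnings(cor(month, as.numeric(emitted), method = "spearman")), 0)
})

test_that("ground truth round-trips losslessly through TSV", {
  sim <- generate_cohort(small_scenario(120), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(nrow(back), 120L)
  for (cl in names(sim$truth)) {
    if (is.factor(sim$truth[[cl]])) {
      expect_equal(as.character(back[[cl]]), as.character(sim$truth[[cl]]))
    } else {
      expect_equal(back[[cl]], sim$truth[[cl]], tolerance = 1e-12, label = cl)
    }
  }
  tg <- attr(back, "scenario_targets")
  expect_equal(tg$rate_nonplacebo, 0.047)
  expect_equal(attr(back, "seed"), 2L)

  # empty truth: header-only body
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_truth(generate_cohort(scenario_config(n_users = 0), seed = 1)$truth, p2)
  expect_equal(nrow(read_truth(p2)), 0L)

  sim3 <- generate_cohort(small_scenario(3), seed = 4)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim3$truth, p3)
  expect_equal(nrow(read_truth(p3)), 3L)
})

test_that("malformed truth files error with a line hint", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#seed 1", "user_id\tage", "u1\t20\t99\tbad"), path)
  expect_error(read_truth(path), "line")
})
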