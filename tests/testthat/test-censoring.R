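test_that("the week distribution is simple counting", {
  d <- estimate_week_distribution(c(4L, 4L, 8L, 12L))
  expect_equal(d$week, c(4L, 8L, 12L))
  expect_equal(d$p, c(0.5, 0.25, 0.25))
  expect_equal(sum(d$p), 1)

  d1 <- estimate_week_distribution(rep(10L, 5))
  expect_equal(d1$p, 1)

  expect_error(estimate_week_distribution(integer(0)), "prior")

  # from a classified log: only pregnancy_week rows count
  log <- dplyr::bind_rows(
    mini_log("a", "2018-02-01 00:00:00", "pregnancy_week", pregnancy_week = 9),
    mini_log("a", "2018-02-08 00:00:00", "pregnancy_week", pregnancy_week = 10),
    mini_log("b", "2018-02-01 00:00:00", "missed_oc")
  )
  d2 <- estimate_week_distribution(log)
  expect_equal(attr(d2, "n_queries"), 2L)
  expect_equal(d2$p, c(0.5, 0.5))
})

test_that("weights enumerate observable weeks against the window end", {
  end <- as.Date("2018-12-31")
  # support up to 40 weeks, index Jan 15: everything observable -> weight 1
  dist40 <- estimate_week_distribution(rep(4:40, 3))
  expect_equal(compute_weight(as.Date("2018-01-15"), dist40, end), 1)

  # uniform over weeks 4..39: from Dec 1 only week 4 (Dec 29) fits
  distu <- estimate_week_distribution(4:39)
  expect_equal(
    compute_weight(as.Date("2018-12-01"), distu, end),
    1 / 36,
    tolerance = 1e-12
  )

  # index at the window end with no mass at week 0 -> floored at epsilon
  expect_equal(compute_weight(end, distu, end), 0.01)
  expect_equal(compute_weight(end, distu, end, weight_floor = 0), 0)
})

test_that("weights match a brute-force day-by-day oracle on tiny cohorts", {
  set.seed(99)
  end <- as.Date("2018-12-31")
  for (rep in 1:10) {
    weeks <- sample(1:45, sample(3:8, 1))
    counts <- sample(1:5, length(weeks), replace = TRUE)
    dist <- estimate_week_distribution(rep(weeks, counts))
    idx <- as.Date("2018-01-01") + sample(0:364, sample(5:20, 1))
    got <- compute_weight(idx, dist, end, weight_floor = 0)
    # oracle: walk each week's query date forward day by day
    oracle <- vapply(idx, function(d0) {
      w <- 0
      for (j in seq_along(dist$week)) {
        qd <- d0
        for (s in seq_len(7 * dist$week[j])) qd <- qd + 1
        if (qd <= end) w <- w + dist$p[j]
      }
      w
    }, 0)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("weights are non-increasing in the index date", {
  dist <- estimate_week_distribution(rep(4:30, 2))
  idx <- seq(as.Date("2018-01-01"), as.Date("2018-12-31"), by = "day")
  w <- compute_weight(idx, dist, as.Date("2018-12-31"))
  expect_true(all(diff(w) <= 1e-12))
  expect_equal(w[1], 1)
})

test_that("the weighted rate divides pregnancies by effective cohort size", {
  r <- weighted_pregnancy_rate(c(1, 1), c(TRUE, FALSE))
  expect_equal(r$weighted, 0.5)
  expect_equal(r$unweighted, 0.5)

  r2 <- weighted_pregnancy_rate(c(1, 0.5, 0.5), c(TRUE, FALSE, FALSE))
  expect_equal(r2$weighted, 0.5)
  expect_equal(r2$unweighted, 1 / 3, tolerance = 1e-12)
  expect_equal(r2$effective_n, 2)

  expect_error(weighted_pregnancy_rate(c(1, 1.2), c(TRUE, FALSE)), "\\(0, 1\\]")
  expect_error(weighted_pregnancy_rate(c(0, 1), c(TRUE, FALSE)), "\\(0, 1\\]")

  # whenever any weight < 1, weighted >= unweighted
  set.seed(4)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    w <- pmax(runif(n), 0.01)
    p <- runif(n) < 0.3
    r <- weighted_pregnancy_rate(w, p)
    expect_gte(r$weighted + 1e-12, r$unweighted)
  }

  # both-sides variant inflates the numerator by inverse weights
  rb <- weighted_pregnancy_rate(c(1, 0.5, 0.5), c(FALSE, TRUE, FALSE),
    both_sides = TRUE
  )
  expect_equal(rb$weighted, 2 / 2)
})

test_that("subgroup rates respect stratum definitions and symmetry", {
  users <- tibble::tibble(
    weight = rep(1, 8),
    pregnant = rep(c(TRUE, FALSE, FALSE, FALSE), 2),
    pill_combined = rep(c(TRUE, FALSE), each = 4),
    pill_progestin = rep(c(FALSE, TRUE), each = 4),
    placebo_mentioned = FALSE,
    n_missed_doses = NA_integer_
  )
  r <- subgroup_rates(users, "pill_type", min_stratum = 1)
  expect_equal(
    r$weighted_rate[r$stratum == "combined"],
    r$weighted_rate[r$stratum == "progestin_only"]
  )
  expect_equal(r$n_users[r$stratum == "unspecified"], 0L)

  expect_error(subgroup_rates(users, "age"), "Unknown grouping")

  # a user mentioning both types lands in both pill strata
  users$pill_progestin <- TRUE
  r2 <- subgroup_rates(users, "pill_type", min_stratum = 1)
  expect_equal(r2$n_users[r2$stratum == "combined"], 4L)
  expect_equal(r2$n_users[r2$stratum == "progestin_only"], 8L)

  # small-stratum flag
  r3 <- subgroup_rates(users, "placebo", min_stratum = 50)
  expect_true(all(r3$small))
})

test_that("weighted and unweighted rates coincide on an uncensored cohort", {
  cfg <- scenario_config(
    n_users = 2500,
    index_start = "2018-01-01", index_end = "2018-01-31"
  )
  sim <- generate_cohort(cfg, seed = 6)
  rep <- suppressMessages(analyze_cohort(sim$log))
  ov <- rep$rates$overall
  expect_equal(ov$weighted, ov$unweighted, tolerance = 1e-12)
  expect_equal(ov$effective_n, ov$n_users)
})

test_that("the bootstrap CI brackets the point estimate", {
  set.seed(12)
  w <- pmax(runif(300), 0.01)
  p <- runif(300) < 0.1
  ci <- bootstrap_rate_ci(w, p, n_boot = 100)
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
})
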