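test_that("timelines anchor at the first missed-OC query", {
  log <- dplyr::bind_rows(
    mini_log("a", "2018-02-01 10:00:00", "missed_oc"),
    mini_log("a", "2018-02-03 10:00:00", "abortion"),
    mini_log("b", "2018-02-01 09:00:00", "abortion"), # no index event
    mini_log("c", "2018-02-05 08:00:00", "missed_oc"),
    mini_log("c", "2018-02-03 08:00:00", "abortion") # precedes index
  )
  tl <- suppressMessages(build_timelines(log))
  expect_equal(nrow(tl$users), 2L)
  expect_equal(tl$n_dropped, 1L)
  expect_equal(
    tl$followups$gap_days[tl$followups$user_id == "a"], 2,
    tolerance = 1e-9
  )
  expect_false("c" %in% tl$followups$user_id)
})

test_that("a second missed-OC query does not re-anchor the timeline", {
  log <- dplyr::bind_rows(
    mini_log("a", "2018-02-01 10:00:00", "missed_oc"),
    mini_log("a", "2018-05-01 10:00:00", "missed_oc"),
    mini_log("a", "2018-05-02 10:00:00", "miscarriage")
  )
  tl <- build_timelines(log)
  expect_equal(tl$users$index_date, as.Date("2018-02-01"))
  expect_equal(tl$followups$gap_days, 90, tolerance = 1e-9)
})

test_that("same-timestamp follow-ups count with gap zero", {
  log <- dplyr::bind_rows(
    mini_log("a", "2018-02-01 10:00:00", "missed_oc"),
    mini_log("a", "2018-02-01 10:00:00", "emergency_contraception")
  )
  tl <- build_timelines(log)
  expect_equal(tl$followups$gap_days, 0)
  gs <- gap_stats(tl, "emergency_contraception")
  expect_equal(gs$fraction_within_24h, 1)
})

test_that("gap statistics use lower-interpolated medians and strict 24h cut", {
  gaps <- c(0.5, 2, 11, 30, 40)
  log <- dplyr::bind_rows(
    lapply(seq_along(gaps), function(i) {
      dplyr::bind_rows(
        mini_log(paste0("u", i), "2018-02-01 00:00:00", "missed_oc"),
        mini_log(
          paste0("u", i),
          format(
            ts_utc("2018-02-01 00:00:00") + gaps[i] * 86400,
            "%Y-%m-%d %H:%M:%S"
          ),
          "abortion"
        )
      )
    })
  )
  gs <- gap_stats(build_timelines(log), "abortion")
  expect_equal(gs$median_gap_days, 11, tolerance = 1e-9)
  expect_equal(gs$fraction_within_24h, 0.2)

  # single gap
  one <- dplyr::bind_rows(
    mini_log("x", "2018-02-01 00:00:00", "missed_oc"),
    mini_log("x", "2018-02-01 02:24:00", "miscarriage")
  )
  gs1 <- gap_stats(build_timelines(one), "miscarriage")
  expect_equal(gs1$median_gap_days, 0.1, tolerance = 1e-9)
  expect_equal(gs1$fraction_within_24h, 1)

  # even count -> lower middle value
  even <- dplyr::bind_rows(
    lapply(1:4, function(i) {
      dplyr::bind_rows(
        mini_log(paste0("e", i), "2018-02-01 00:00:00", "missed_oc"),
        mini_log(
          paste0("e", i),
          format(ts_utc("2018-02-01 00:00:00") + i * 86400, "%Y-%m-%d %H:%M:%S"),
          "abortion"
        )
      )
    })
  )
  expect_equal(gap_stats(build_timelines(even), "abortion")$median_gap_days, 2)

  # empty class is an explicit empty result, not an error
  gs0 <- gap_stats(build_timelines(one), "abortion")
  expect_equal(gs0$n, 0L)
  expect_true(is.na(gs0$median_gap_days))
})

test_that("followed_by_pregnancy requires strict ordering", {
  log1 <- dplyr::bind_rows(
    mini_log("a", "2018-01-01 00:00:00", "missed_oc"),
    mini_log("a", "2018-01-02 00:00:00", "abortion"),
    mini_log("a", "2018-02-10 00:00:00", "pregnancy_week", pregnancy_week = 6)
  )
  expect_equal(followed_by_pregnancy(build_timelines(log1), "abortion"), 1L)

  log2 <- dplyr::bind_rows(
    mini_log("a", "2018-01-01 00:00:00", "missed_oc"),
    mini_log("a", "2018-02-10 00:00:00", "pregnancy_week", pregnancy_week = 6),
    mini_log("a", "2018-02-11 00:00:00", "abortion")
  )
  expect_equal(followed_by_pregnancy(build_timelines(log2), "abortion"), 0L)

  log3 <- dplyr::bind_rows(
    mini_log("a", "2018-01-01 00:00:00", "missed_oc"),
    mini_log("a", "2018-01-02 00:00:00", "abortion")
  )
  expect_equal(followed_by_pregnancy(build_timelines(log3), "abortion"), 0L)
})

test_that("follow-up counts are invariant to non-index users and tie order", {
  set.seed(31)
  sim <- generate_cohort(small_scenario(300), seed = 8)
  cl <- classify_queries(sim$log)
  tl <- suppressMessages(build_timelines(cl))
  # drop rows of users with no missed-OC query (background/other users)
  cohort_ids <- unique(cl$user_id[cl$label == "missed_oc"])
  cl2 <- cl[cl$user_id %in% cohort_ids, , drop = FALSE]
  tl2 <- build_timelines(cl2)
  expect_equal(followup_summary(tl), followup_summary(tl2))

  # shuffle rows (stable ordering restores identical timelines)
  cl3 <- cl2[sample.int(nrow(cl2)), , drop = FALSE]
  tl3 <- build_timelines(cl3)
  expect_equal(
    dplyr::arrange(tl2$followups, user_id, label)$gap_days,
    dplyr::arrange(tl3$followups, user_id, label)$gap_days
  )
})

test_that("the follow-up summary is internally consistent", {
  sim <- generate_cohort(small_scenario(400), seed = 13)
  cl <- classify_queries(sim$log)
  tl <- suppressMessages(build_timelines(cl))
  fs <- followup_summary(tl)
  expect_equal(nrow(fs), 4L)
  expect_true(all(fs$n_users_with_followup <= nrow(tl$users)))
  expect_true(all(fs$fraction_of_missed_users >= 0 &
    fs$fraction_of_missed_users <= 1))
  for (i in seq_len(nrow(fs))) {
    expect_equal(
      fs$n_users_with_followup[i],
      sum(tl$followups$label == fs$class[i])
    )
  }
  expect_true(all(fs$median_gap_days >= 0, na.rm = TRUE))
})
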