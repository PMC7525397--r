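test_that("each query class is recognised from its trigger phrases", {
  cases <- list(
    list("i forgot my birth control pill yesterday", "missed_oc"),
    list("missed my yaz pill this morning", "missed_oc"),
    list("skipped a minipill dose", "missed_oc"),
    list("what to do if i missed 2 contraceptive pills", "missed_oc"),
    list("what to expect on week 21 of pregnancy", "pregnancy_week"),
    list("pregnancy week 10 symptoms", "pregnancy_week"),
    list("21 weeks pregnant what to expect", "pregnancy_week"),
    list("plan b price near me", "emergency_contraception"),
    list("where to buy the morning after pill", "emergency_contraception"),
    list("cramping after miscarriage", "miscarriage"),
    list("i had a miscarriage what now", "miscarriage"),
    list("post miscarriage care", "miscarriage"),
    list("abortion clinic near me", "abortion"),
    list("how much does an abortion cost", "abortion"),
    list("weather tomorrow", "other"),
    list("   ", "other")
  )
  for (cs in cases) {
    got <- classify_query(cs[[1]])
    expect_equal(as.character(got$label), cs[[2]], label = cs[[1]])
  }
})

test_that("exclusion phrases suppress abortion and EC labels", {
  excl <- c(
    "abortion law debate 2018",
    "abortion ban in the senate",
    "supreme court abortion case",
    "celebrity who had an abortion",
    "plan b legislation news",
    "morning after pill legal debate"
  )
  for (q in excl) {
    expect_equal(as.character(classify_query(q)$label), "other", label = q)
  }
  # the exclusion must not bleed into other classes
  expect_equal(
    as.character(classify_query("i forgot my birth control in a legal mess")$label),
    "missed_oc"
  )
})

test_that("precedence is total: missed_oc beats all, pregnancy_week next", {
  expect_equal(
    as.character(
      classify_query("forgot my birth control should i take plan b")$label
    ),
    "missed_oc"
  )
  expect_equal(
    as.character(
      classify_query("missed birth control now 6 weeks of pregnancy")$label
    ),
    "missed_oc"
  )
  expect_equal(
    as.character(
      classify_query("week 8 of pregnancy after taking plan b")$label
    ),
    "pregnancy_week" # pregnancy_week outranks emergency_contraception
  )
  expect_equal(
    as.character(
      classify_query("plan b after miscarriage and abortion questions")$label
    ),
    "emergency_contraception" # EC outranks miscarriage and abortion
  )
})

test_that("pregnancy_week requires an extractable in-range week number", {
  expect_equal(
    as.character(classify_query("weeks until pregnancy test works")$label),
    "other"
  )
  expect_equal(
    as.character(classify_query("week 99 of pregnancy")$label),
    "other"
  )
  expect_equal(classify_query("week 8 of pregnancy after taking plan b")$pregnancy_week, 8L)
})

test_that("classification is deterministic and case-insensitive", {
  txts <- c(
    "I FORGOT MY BIRTH CONTROL PILL", "Pregnancy Week 12 Symptoms",
    "PLAN B Price", "Cramping AFTER MISCARRIAGE", "ABORTION Clinic near me",
    "Weather TOMORROW"
  )
  a <- classify_queries(tibble::tibble(text = txts))
  b <- classify_queries(tibble::tibble(text = tolower(txts)))
  expect_identical(as.character(a$label), as.character(b$label))
  expect_identical(a$label, classify_queries(tibble::tibble(text = txts))$label)
  # exactly one label per query, always
  expect_false(any(is.na(a$label)))
})

test_that("missed-dose attributes are extracted from text", {
  a <- extract_missed_attrs("forgot 2 birth control pills in a row")
  expect_equal(a$n_missed_doses, 2L)
  expect_equal(as.character(a$pill_type), "unspecified")
  expect_false(a$placebo_mentioned)

  expect_true(extract_missed_attrs("missed my placebo pill does it matter")$placebo_mentioned)
  expect_true(extract_missed_attrs("missed a sugar pill of my pack")$placebo_mentioned)

  b <- extract_missed_attrs("skipped a minipill dose")
  expect_equal(as.character(b$pill_type), "progestin_only")

  cc <- extract_missed_attrs("missed two doses of yaz and my camila")
  expect_equal(cc$n_missed_doses, 2L)
  expect_equal(as.character(cc$pill_type), "both")
  expect_true(cc$pill_combined && cc$pill_progestin)

  expect_true(is.na(extract_missed_attrs("missed my birth control")$n_missed_doses))
})

test_that("pregnancy week extraction handles both orders and rejects unattached numbers", {
  expect_equal(extract_pregnancy_week("pregnancy week 10 symptoms"), 10L)
  expect_equal(extract_pregnancy_week("21 weeks pregnant what to expect"), 21L)
  expect_equal(extract_pregnancy_week("week 45 of pregnancy"), 45L)
  expect_true(is.na(extract_pregnancy_week("weeks until pregnancy test works")))
  expect_true(is.na(extract_pregnancy_week("week 50 of pregnancy")))
  expect_true(is.na(extract_pregnancy_week("i am 2018 weeks old")))
})

test_that("a missing lexicon entry is a configuration error", {
  lex <- oc_lexicon()
  lex$brands_combined <- NULL
  expect_error(
    classify_queries(tibble::tibble(text = "x"), lex),
    "missing required"
  )
  # but arbitrary text never raises
  weird <- tibble::tibble(text = c("", "ééé", "((((", "NA", "0"))
  expect_silent(classify_queries(weird))
})

test_that("lexicon round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lexicon(oc_lexicon(), path)
  lex <- read_lexicon(path)
  expect_equal(lex$brands_combined, oc_lexicon()$brands_combined)
  expect_equal(lex$number_words, oc_lexicon()$number_words)
})
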