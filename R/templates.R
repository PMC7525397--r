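# Query-text templates for the synthetic generator. Each template embeds an
# unambiguous trigger phrase for its intended class and avoids the trigger
# and exclusion vocabulary of every other class, so the rule-based
# classifier recovers generator intents exactly. Robustness of the
# classifier to real linguistic variation is deliberately not modelled.

missed_triggers <- c(
  "missed", "i missed", "forgot", "i forgot", "skipped", "i skipped",
  "what to do if i missed", "help i forgot", "accidentally skipped"
)

missed_tails <- c(
  "", "yesterday", "what should i do", "last night", "this month",
  "am i protected", "do i need backup"
)

num_token <- function(n, as_word) {
  words <- c("one", "two", "three", "four", "five", "six")
  ifelse(as_word & n <= 6, words[n], as.character(n))
}

# core pill phrase by mention class; `plural` forms carry a stated dose
pill_phrase <- function(pill_class, brand_c, brand_p, n_tok = NULL) {
  if (is.null(n_tok)) {
    switch(pill_class,
      none = sample(c(
        "my birth control", "my birth control pill", "a contraceptive pill",
        "my birth control this morning"
      ), 1),
      combined_only = sample(c(
        paste("my", brand_c, "pill"), paste("my", brand_c, "birth control"),
        paste0("my ", brand_c)
      ), 1),
      progestin_only = sample(c(
        "my minipill", paste("my", brand_p), "a minipill dose",
        paste("my", brand_p, "minipill")
      ), 1),
      both = sample(c(
        paste0("my ", brand_c, " and my minipill"),
        paste0("my ", brand_c, " pill and my ", brand_p)
      ), 1)
    )
  } else {
    switch(pill_class,
      none = sample(c(
        paste(n_tok, "birth control pills"),
        paste(n_tok, "doses of my birth control"),
        paste(n_tok, "pills of my birth control")
      ), 1),
      combined_only = sample(c(
        paste(n_tok, brand_c, "pills"),
        paste(n_tok, "doses of", brand_c)
      ), 1),
      progestin_only = sample(c(
        paste(n_tok, "minipill doses"),
        paste(n_tok, "doses of my minipill"),
        paste(n_tok, brand_p, "pills")
      ), 1),
      both = sample(c(
        paste(n_tok, brand_c, "pills and my minipill"),
        paste(n_tok, "doses of", brand_c, "and my", brand_p)
      ), 1)
    )
  }
}

placebo_phrase <- function(n_tok = NULL) {
  if (is.null(n_tok)) {
    sample(c(
      "my placebo pill of my birth control pack",
      "a placebo pill from my birth control pack",
      "my birth control placebo pill",
      "a sugar pill of my birth control"
    ), 1)
  } else {
    sample(c(
      paste(n_tok, "placebo pill of my birth control pack"),
      paste(n_tok, "sugar pill from my birth control")
    ), 1)
  }
}

missed_query_text <- function(config, dose_cat, n_doses, pill_class, placebo) {
  lex <- oc_lexicon()
  n <- length(dose_cat)
  trig <- sample(missed_triggers, n, replace = TRUE)
  tail <- sample(missed_tails, n, replace = TRUE)
  brand_c <- sample(lex$brands_combined, n, replace = TRUE)
  brand_p <- sample(lex$brands_progestin, n, replace = TRUE)
  as_word <- runif(n) < 0.3
  core <- character(n)
  for (i in seq_len(n)) {
    n_tok <- if (!is.na(n_doses[i])) num_token(n_doses[i], as_word[i]) else NULL
    core[i] <- if (placebo[i]) {
      placebo_phrase(n_tok)
    } else {
      pill_phrase(pill_class[i], brand_c[i], brand_p[i], n_tok)
    }
  }
  trimws(paste(trig, core, tail))
}

followup_templates <- list(
  miscarriage = c(
    "cramping after miscarriage",
    "period after miscarriage when",
    "i had a miscarriage what now",
    "post miscarriage care",
    "bleeding after miscarriage how long",
    "i had a miscarriage when can i try again",
    "post miscarriage recovery time",
    "pain after miscarriage normal",
    "i had a miscarriage last week is that common",
    "diet after miscarriage"
  ),
  abortion = c(
    "abortion clinic near me",
    "how much does an abortion cost",
    "abortion pill how does it work",
    "where can i get an abortion",
    "how late can you get an abortion",
    "does insurance cover abortion",
    "abortion procedure what to expect",
    "abortion pill vs procedure",
    "abortion recovery time",
    "closest abortion provider"
  ),
  emergency_contraception = c(
    "plan b near me",
    "how effective is plan b",
    "morning after pill side effects",
    "where to buy the morning after pill",
    "plan b price",
    "how long does plan b work",
    "morning after pill cost",
    "does the morning after pill always work",
    "plan b how soon do i have to take it",
    "morning after pill over the counter"
  )
)

followup_query_text <- function(cls, k) {
  sample(followup_templates[[cls]], k, replace = TRUE)
}

pregnancy_query_text <- function(weeks) {
  k <- length(weeks)
  tpl <- sample.int(6L, k, replace = TRUE)
  out <- character(k)
  out[tpl == 1] <- sprintf("pregnancy week %d symptoms", weeks[tpl == 1])
  out[tpl == 2] <- sprintf(
    "what to expect on week %d of pregnancy", weeks[tpl == 2]
  )
  out[tpl == 3] <- sprintf("%d weeks pregnant what to expect", weeks[tpl == 3])
  out[tpl == 4] <- sprintf("pregnancy symptoms week %d", weeks[tpl == 4])
  out[tpl == 5] <- sprintf("baby size at %d weeks of pregnancy", weeks[tpl == 5])
  out[tpl == 6] <- sprintf("week %d of pregnancy what is happening", weeks[tpl == 6])
  out
}

other_templates <- c(
  "weather tomorrow",
  "cheap flights to orlando",
  "best pizza near me",
  "football scores today",
  "how to fix a flat tire",
  "movie showtimes this weekend",
  "laptop deals",
  "banana bread recipe",
  "traffic to downtown",
  "dog friendly parks nearby"
)

other_query_text <- function(k) {
  sample(other_templates, k, replace = TRUE)
}
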