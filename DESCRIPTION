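Package: ocquery
Title: Search-Engine Query-Log Analysis of Missed Oral-Contraceptive Doses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for infodemiology studies of missed oral-contraceptive (OC)
    doses in search-engine query logs. Classifies queries into five classes
    (missed OC dose, miscarriage, abortion, emergency contraception, pregnancy
    week) with a rule-based lexicon, links follow-up queries per user, infers
    last-menstrual-period dates from reported gestational weeks, and estimates
    right-censoring-corrected ("weighted") pregnancy rates overall and by
    subgroup, together with gap-time and age-stratified statistics. Includes a
    synthetic query-log generator with a ground-truth sidecar so that every
    estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
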