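#' Normalize query text
#'
#' Lower-cases, strips punctuation except hyphens, collapses whitespace and
#' trims. No spelling correction is attempted.
#'
#' @param text Character vector of raw query strings.
#' @return Character vector of normalized strings.
#' @export
normalize_query_text <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("[^a-z0-9 -]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# word-boundary alternation regex from a vector of (possibly multi-word) terms
term_regex <- function(terms) {
  esc <- gsub("([.|()\\^{}+$*?\\[\\]])", "\\\\\\1", terms)
  paste0("\\b(?:", paste(esc, collapse = "|"), ")\\b")
}

miss_trigger_regex <- function(lexicon) {
  # stem-style prefix match: miss/missed/missing, skip/skipped, forgot/
  # forgotten/forget(ting). "miscarriage" does not match (single 's').
  "\\b(?:miss[a-z]*|skip[a-z]*|forg[eo]t[a-z]*)\\b"
}

oc_term_regex <- function(lexicon) {
  terms <- c(
    lexicon$brands_combined, lexicon$brands_progestin,
    "mini ?pills?", "birth control", "contracepti[a-z]*"
  )
  # brand names are literal; the last three carry their own regex syntax
  lit <- term_regex(c(lexicon$brands_combined, lexicon$brands_progestin))
  paste0(lit, "|\\bmini ?pills?\\b|\\bbirth control\\b|\\bcontracepti[a-z]*\\b")
}

exclusion_regex <- function(lexicon) {
  term_regex(c(lexicon$exclusion_terms, lexicon$celebrity_terms))
}

#' Extract a reported pregnancy week from query text
#'
#' Returns the first integer in `[1, 45]` syntactically attached to
#' "week"/"weeks" (as in "week 21" or "21 weeks"). Ordinal words
#' ("twentieth week") are not parsed.
#'
#' @param text Character vector (raw or normalized query text).
#' @return Integer vector; `NA` where no attached in-range week is found.
#' @export
extract_pregnancy_week <- function(text) {
  x <- normalize_query_text(text)
  out <- rep(NA_integer_, length(x))
  cand <- grepl("\\bweeks?\\b", x) & grepl("[0-9]", x)
  if (!any(cand)) return(out)
  pat <- "\\bweeks?\\s+([0-9]{1,2})\\b|\\b([0-9]{1,2})\\s+weeks?\\b"
  hits <- gregexpr(pat, x[cand], perl = TRUE)
  vals <- mapply(function(s, m) {
    if (m[[1]][1] == -1) return(NA_integer_)
    for (piece in regmatches(s, list(m))[[1]]) {
      num <- as.integer(gsub("[^0-9]", "", piece))
      if (!is.na(num) && num >= 1L && num <= 45L) return(num)
    }
    NA_integer_
  }, x[cand], hits, USE.NAMES = FALSE)
  out[cand] <- vals
  out
}

#' Extract missed-dose attributes from a missed-OC query
#'
#' Parses the number of missed doses (digits or number words adjacent to a
#' pill/dose term), the mentioned pill type (from the brand lexicon; the
#' token "minipill" implies progestin-only), and whether a placebo pill is
#' mentioned. A query can mention both a combined brand and a progestin-only
#' product; both flags are then set.
#'
#' @param text Character vector of query text (assumed classified missed_oc,
#'   but safe on arbitrary text).
#' @param lexicon An [oc_lexicon()] list.
#' @return A tibble with columns `n_missed_doses` (integer, `NA` when not
#'   stated), `pill_combined`, `pill_progestin`, `placebo_mentioned`
#'   (logicals) and `pill_type` (factor: combined / progestin_only / both /
#'   unspecified).
#' @export
extract_missed_attrs <- function(text, lexicon = oc_lexicon()) {
  validate_lexicon(lexicon)
  x <- normalize_query_text(text)
  comb <- grepl(term_regex(lexicon$brands_combined), x, perl = TRUE)
  prog <- grepl(term_regex(lexicon$brands_progestin), x, perl = TRUE) |
    grepl("\\bmini ?pills?\\b", x, perl = TRUE)
  placebo <- grepl("\\bplacebo\\b|\\bsugar pill\\b", x, perl = TRUE)

  words <- paste(names(lexicon$number_words), collapse = "|")
  pat <- paste0(
    "\\b([0-9]{1,2}|", words, ")\\b(?:\\s+\\S+){0,3}?\\s+",
    "(?:pills?|doses?|tablets?)\\b"
  )
  m <- regexpr(pat, x, perl = TRUE)
  n_doses <- rep(NA_integer_, length(x))
  hit <- m != -1L
  if (any(hit)) {
    cs <- attr(m, "capture.start")[hit, 1]
    cl <- attr(m, "capture.length")[hit, 1]
    tok <- substr(x[hit], cs, cs + cl - 1L)
    num <- suppressWarnings(as.integer(tok))
    widx <- match(tok, names(lexicon$number_words))
    num[is.na(num)] <- as.integer(lexicon$number_words[widx[is.na(num)]])
    num[!is.na(num) & (num < 1L | num > 30L)] <- NA_integer_
    n_doses[hit] <- num
  }
  pill_type <- factor(
    ifelse(comb & prog, "both",
      ifelse(comb, "combined",
        ifelse(prog, "progestin_only", "unspecified")
      )
    ),
    levels = c("combined", "progestin_only", "both", "unspecified")
  )
  tibble(
    n_missed_doses = n_doses,
    pill_combined = comb,
    pill_progestin = prog,
    placebo_mentioned = placebo,
    pill_type = pill_type
  )
}

#' Classify queries into the five study classes
#'
#' Deterministic keyword classification of free-text queries:
#' \describe{
#'   \item{missed_oc}{a variant of miss/skip/forgot together with an OC brand
#'     name or a generic OC term ("birth control", "contraceptive",
#'     "minipill").}
#'   \item{miscarriage}{"after miscarriage", "post miscarriage" or
#'     "i had a miscarriage".}
#'   \item{abortion}{the word "abortion", excluding legislation / debate /
#'     celebrity queries (exclusion keyword lists).}
#'   \item{emergency_contraception}{"plan b" or "morning after pill", with the
#'     same exclusions.}
#'   \item{pregnancy_week}{the words "week" and "pregnancy" (any order) with
#'     an extractable week number in 1--45.}
#' }
#' Everything else is `other`. Matching is case-insensitive on normalized
#' text. When several rules fire, precedence is missed_oc > pregnancy_week >
#' emergency_contraception > miscarriage > abortion: a query mentioning a
#' missed pill is the index event of interest and always wins.
#'
#' @param log A data frame with at least a `text` column (a query log as
#'   returned by [read_query_log()] or [generate_cohort()]).
#' @param lexicon An [oc_lexicon()] list.
#' @return The input as a tibble with added columns `label` (factor over the
#'   six classes), `pregnancy_week` (integer, set iff label is
#'   pregnancy_week), and the [extract_missed_attrs()] columns (set iff label
#'   is missed_oc).
#' @export
#' @examples
#' classify_queries(tibble::tibble(text = c(
#'   "i forgot my birth control pill yesterday",
#'   "what to expect on week 21 of pregnancy",
#'   "abortion law debate 2018"
#' )))
classify_queries <- function(log, lexicon = oc_lexicon()) {
  validate_lexicon(lexicon)
  log <- as_tibble(log)
  if (!"text" %in% names(log)) abort("`log` must have a `text` column.")
  x <- normalize_query_text(log$text)

  trig <- grepl(miss_trigger_regex(lexicon), x, perl = TRUE)
  octerm <- grepl(oc_term_regex(lexicon), x, perl = TRUE)
  missed <- trig & octerm

  week_no <- rep(NA_integer_, length(x))
  preg_cand <- grepl("\\bweeks?\\b", x) & grepl("\\bpregnan[a-z]*\\b", x)
  if (any(preg_cand)) week_no[preg_cand] <- extract_pregnancy_week(x[preg_cand])
  pregw <- preg_cand & !is.na(week_no)

  excl <- grepl(exclusion_regex(lexicon), x, perl = TRUE)
  ec <- grepl(term_regex(lexicon$ec_phrases), x, perl = TRUE) & !excl
  misc <- grepl(paste(lexicon$miscarriage_phrases, collapse = "|"), x)
  abo <- grepl("\\babortions?\\b", x, perl = TRUE) & !excl

  lvl <- c(
    "missed_oc", "pregnancy_week", "emergency_contraception",
    "miscarriage", "abortion", "other"
  )
  lab <- rep(6L, length(x))
  lab[abo] <- 5L
  lab[misc] <- 4L
  lab[ec] <- 3L
  lab[pregw] <- 2L
  lab[missed] <- 1L
  label <- factor(lvl[lab], levels = lvl)

  attrs <- tibble(
    n_missed_doses = rep(NA_integer_, length(x)),
    pill_combined = rep(NA, length(x)),
    pill_progestin = rep(NA, length(x)),
    placebo_mentioned = rep(NA, length(x)),
    pill_type = factor(rep(NA_character_, length(x)),
      levels = c("combined", "progestin_only", "both", "unspecified")
    )
  )
  if (any(missed)) attrs[missed, ] <- extract_missed_attrs(x[missed], lexicon)

  # re-classifying an already-classified log replaces stale columns
  out <- log[setdiff(names(log), c("label", "pregnancy_week", names(attrs)))]
  out$label <- label
  out$pregnancy_week <- ifelse(pregw, week_no, NA_integer_)
  out <- dplyr::bind_cols(out, attrs)
  out
}

#' Classify a single query string
#'
#' Convenience wrapper around [classify_queries()] for one query.
#'
#' @param text A single query string.
#' @inheritParams classify_queries
#' @return A one-row tibble with `label` and extracted attributes.
#' @export
classify_query <- function(text, lexicon = oc_lexicon()) {
  stopifnot(length(text) == 1L)
  classify_queries(tibble(text = as.character(text)), lexicon)
}
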