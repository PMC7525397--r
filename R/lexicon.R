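#' Default classification lexicon
#'
#' Keyword lists driving the rule-based query classifier. The five query
#' classes are triggered by fixed keyword rules; the lexicon supplies the
#' editable parts: OC brand names (combined and progestin-only), generic OC
#' terms, exclusion keywords for the abortion / emergency-contraception rules
#' (legislation, debates, celebrities), and the number words recognised when
#' extracting missed-dose counts.
#'
#' Brand lists are deliberately editable data, not code: deployments can load
#' a site-specific lexicon with [read_lexicon()]. The shipped lists contain
#' common US brand names; classifier tests rely only on the generic triggers
#' ("birth control", "contraceptive", "minipill"), so lexicon content can be
#' swapped without invalidating the analysis.
#'
#' @return A named list of character vectors with class `oc_lexicon`.
#' @export
#' @examples
#' lex <- oc_lexicon()
#' names(lex)
oc_lexicon <- function() {
  lex <- list(
    miss_triggers = c("miss", "skip", "forget", "forgot", "forgotten"),
    oc_generic = c("birth control", "contraceptive", "minipill"),
    brands_combined = c(
      "yaz", "yasmin", "alesse", "sprintec", "junel", "levora",
      "estarylla", "seasonique", "lo loestrin", "ortho tri-cyclen",
      "apri", "aviane"
    ),
    brands_progestin = c(
      "micronor", "camila", "errin", "heather", "nora-be", "jolivette",
      "norethindrone", "slynd"
    ),
    miscarriage_phrases = c(
      "after miscarriage", "post miscarriage", "i had a miscarriage"
    ),
    ec_phrases = c("plan b", "morning after pill"),
    exclusion_terms = c(
      "law", "laws", "legal", "illegal", "legislation", "ban", "bans",
      "banned", "debate", "court", "senate", "supreme", "election",
      "vote", "politics", "protest", "news"
    ),
    celebrity_terms = c("celebrity", "celebrities", "famous", "actress"),
    number_words = c(
      one = 1, two = 2, three = 3, four = 4, five = 5,
      six = 6, seven = 7, eight = 8, nine = 9
    )
  )
  structure(lex, class = "oc_lexicon")
}

required_lexicon_fields <- c(
  "miss_triggers", "oc_generic", "brands_combined", "brands_progestin",
  "miscarriage_phrases", "ec_phrases", "exclusion_terms", "celebrity_terms",
  "number_words"
)

validate_lexicon <- function(lexicon) {
  if (!is.list(lexicon)) {
    abort("`lexicon` must be a list (see `oc_lexicon()`).")
  }
  missing <- setdiff(required_lexicon_fields, names(lexicon))
  if (length(missing) > 0) {
    abort(paste0(
      "Lexicon is missing required entry list(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  nw <- lexicon$number_words
  if (is.null(names(nw)) || !is.numeric(unlist(nw))) {
    abort("`number_words` must be a named numeric vector (word -> value).")
  }
  invisible(lexicon)
}

#' Read or write a lexicon as YAML
#'
#' @param path Path to a YAML file holding the keyword lists. All entries of
#'   [oc_lexicon()] must be present.
#' @return `read_lexicon()` returns an `oc_lexicon` list; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("Lexicon file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$number_words)) {
    raw$number_words <- unlist(raw$number_words)
  }
  validate_lexicon(raw)
  structure(raw, class = "oc_lexicon")
}

#' @rdname read_lexicon
#' @param lexicon An `oc_lexicon` list.
#' @export
write_lexicon <- function(lexicon, path) {
  validate_lexicon(lexicon)
  out <- unclass(lexicon)
  out$number_words <- as.list(out$number_words)
  yaml::write_yaml(out, path)
  invisible(path)
}
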