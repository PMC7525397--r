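#' Tabulate missed-dose attributes over users
#'
#' Percentages are over users (first missed-OC query per user). Pill-type
#' mention percentages may sum above 100% because a user can mention both a
#' combined brand and a progestin-only product; such users count in both
#' categories.
#'
#' @param timelines An [build_timelines()] object.
#' @return A list with `n_users`, `dose_count` (tibble of category and
#'   share), `pill_mention` (shares of no-type / combined / progestin
#'   mentions) and `placebo_fraction`.
#' @export
tabulate_missed <- function(timelines) {
  stopifnot(inherits(timelines, "oc_timelines"))
  u <- timelines$users
  n <- nrow(u)
  if (n == 0) abort("No missed-OC users to tabulate.")
  dose_cat <- ifelse(is.na(u$n_missed_doses), "unspecified",
    ifelse(u$n_missed_doses >= 4L, "4+", as.character(u$n_missed_doses))
  )
  cats <- c("unspecified", "1", "2", "3", "4+")
  dose <- tibble(
    category = cats,
    share = as.numeric(table(factor(dose_cat, levels = cats))) / n
  )
  pill <- c(
    none = mean(!(u$pill_combined %in% TRUE) & !(u$pill_progestin %in% TRUE)),
    combined = mean(u$pill_combined %in% TRUE),
    progestin = mean(u$pill_progestin %in% TRUE)
  )
  list(
    n_users = n,
    dose_count = dose,
    pill_mention = pill,
    placebo_fraction = mean(u$placebo_mentioned %in% TRUE)
  )
}

#' Spearman correlation between age and number of missed doses
#'
#' Rank correlation with average-rank tie handling; the p-value uses the
#' large-sample t approximation. Pairs with either field missing are
#' dropped; an all-tied input yields an absent (`NA`) correlation.
#'
#' @param age,n_doses Numeric vectors of equal length.
#' @return List: `rho`, `p_value`, `n`.
#' @export
age_dose_correlation <- function(age, n_doses) {
  ok <- !is.na(age) & !is.na(n_doses)
  age <- age[ok]
  n_doses <- n_doses[ok]
  n <- length(age)
  if (n < 3 || length(unique(age)) == 1 || length(unique(n_doses)) == 1) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    cor.test(age, n_doses, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

# Pearson chi-square on a 2x2 table without continuity correction,
# closed form: n (ad - bc)^2 / (r1 r2 c1 c2)
chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(list(chi2 = NA_real_, p_value = NA_real_))
  chi2 <- n * (a * d - b * c)^2 / den
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Age-band follow-up ratio with chi-square test
#'
#' Compares the proportion of missed-OC users with at least one follow-up
#' query of a class between an age band and a comparison band (default:
#' the complement of all users with known age). The chi-square statistic
#' is Pearson's on the 2x2 band-by-followup table without continuity
#' correction (configurable), with 1 degree of freedom. Users with missing
#' age are excluded.
#'
#' @param timelines An [build_timelines()] object.
#' @param class Follow-up class (`miscarriage`, `abortion`,
#'   `emergency_contraception`, `pregnancy_week`).
#' @param band Age band of interest: one of the [age_band()] levels or
#'   `"under30"`.
#' @param comparison `"complement"` (default) or a band specification.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A tibble row: bands, per-band counts and proportions, ratio,
#'   chi2, p_value.
#' @export
age_band_ratio <- function(timelines, class, band = "30-34",
                           comparison = "complement", correct = FALSE) {
  stopifnot(inherits(timelines, "oc_timelines"))
  u <- timelines$users
  u <- u[!is.na(u$age), , drop = FALSE]
  bands <- age_band(u$age)
  in_a <- in_band(bands, band)
  in_b <- if (identical(comparison, "complement")) !in_a else in_band(bands, comparison)
  if (sum(in_a) == 0) abort(paste0("Empty age band: ", band))
  if (sum(in_b) == 0) abort(paste0("Empty comparison band: ", comparison))
  has_fu <- u$user_id %in%
    timelines$followups$user_id[timelines$followups$label == class]
  a <- sum(in_a & has_fu)
  b <- sum(in_a & !has_fu)
  c_ <- sum(in_b & has_fu)
  d <- sum(in_b & !has_fu)
  prop_a <- a / (a + b)
  prop_b <- c_ / (c_ + d)
  cs <- if (correct) {
    ct <- suppressWarnings(
      stats::chisq.test(matrix(c(a, b, c_, d), 2, byrow = TRUE), correct = TRUE)
    )
    list(chi2 = unname(ct$statistic), p_value = ct$p.value)
  } else {
    chisq_2x2(a, b, c_, d)
  }
  tibble(
    class = class, band_a = band,
    band_b = if (identical(comparison, "complement")) "complement" else comparison,
    n_a = a + b, n_b = c_ + d,
    proportion_a = prop_a, proportion_b = prop_b,
    ratio = if (prop_b > 0) prop_a / prop_b else NA_real_,
    chi2 = cs$chi2, p_value = cs$p_value
  )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two label vectors using the standard
#' two-rater formula with marginal-product expected agreement. When the
#' expected agreement is 1 (both raters constant and concordant), kappa is
#' reported as 0 by convention.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return A list with `n_items`, `observed_agreement`,
#'   `expected_agreement` and `kappa`.
#' @export
#' @examples
#' cohens_kappa(c(1, 1, 0, 1), c(1, 0, 0, 1))
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must have equal length.")
  }
  n <- length(labels_a)
  if (n < 1) abort("Need at least one item.")
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  po <- mean(a == b)
  lev <- union(unique(a), unique(b))
  pa <- table(factor(a, levels = lev)) / n
  pb <- table(factor(b, levels = lev)) / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) {
    0
  } else {
    (po - pe) / (1 - pe)
  }
  list(
    n_items = n, observed_agreement = po,
    expected_agreement = pe, kappa = kappa
  )
}
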