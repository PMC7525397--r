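---
title: "Censoring-weighted pregnancy rates from missed-pill query logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censoring-weighted pregnancy rates from missed-pill query logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocquery)
```

## The problem

When a woman misses one or more doses of an oral contraceptive (OC), her
search-engine queries in the following weeks and months carry signal about
what happened next: queries about emergency contraception, about abortion or
miscarriage, and — when a pregnancy follows — queries of the form
"pregnancy week 8 symptoms". `ocquery` turns an anonymized per-user query
log into epidemiological summaries of this process:

* rule-based classification of queries into five classes
  (missed OC dose, miscarriage, abortion, emergency contraception,
  pregnancy week);
* per-user timelines anchored at the first missed-OC query (the *index*
  query), with gap-time statistics for each follow-up class;
* gestational dating: each "week *k* of pregnancy" query implies a last
  menstrual period (LMP) of `query date − 7k` days, so recurrent queries
  can be checked for consistency and the pregnancy can be *timed* to the
  cycle of the missed pill;
* a right-censoring correction for the finite observation window, and
  censoring-corrected ("weighted") pregnancy rates overall and by subgroup
  (pill type, placebo mention, number of missed doses);
* age-stratified follow-up comparisons and descriptive statistics.

Because real search logs of this kind are proprietary, the package ships a
synthetic query-log generator whose defaults encode the study conditions
the analysis is designed for. Every estimator is validated by *parameter
recovery*: the pipeline must reproduce the generator's configured truth
from the generated log.

## Query classification

Classification is deterministic keyword matching on normalized text
(lower-case, punctuation stripped except hyphens, whitespace collapsed).
The rules are:

| class | rule |
|---|---|
| missed_oc | a variant of *miss/skip/forgot* **and** an OC term (brand name, "birth control", "contraceptive", "minipill") |
| pregnancy_week | "week" and a "pregnan-" token, with an extractable week number in 1–45 |
| emergency_contraception | "plan b" or "morning after pill", minus exclusions |
| miscarriage | "after miscarriage", "post miscarriage", "i had a miscarriage" |
| abortion | "abortion", minus exclusions |

Exclusion lists (legislation, debates, courts, celebrities) suppress the
abortion and emergency-contraception rules; they are editable data in the
lexicon (`oc_lexicon()`, `inst/extdata/lexicon.yaml`), as are the brand
lists. Word variants are matched by stem prefixes (*missed*, *missing*,
*forgotten*, ...). When several rules fire, precedence is
`missed_oc > pregnancy_week > emergency_contraception > miscarriage >
abortion`: a query mentioning a missed pill is the index event of
interest, and a query that dates a pregnancy is more informative than the
other follow-up classes. The precedence makes the label unique, which the
tests assert as a property.

Missed-dose attributes are parsed from the same text: a dose count
(digits or the number words one–nine adjacent to a pill/dose token), the
mentioned pill type (combined brand list, progestin-only brand list, the
token "minipill"), and a placebo-pill mention. A query can mention both a
combined and a progestin-only product; both flags are then set and such
users count in both pill-type strata, so the pill-type shares may sum
above 100%.

## Timelines and gap times

A user's timeline is anchored at the timestamp of their *first* missed-OC
query. Follow-ups are the first query of each class **at or after** the
index timestamp — inclusive, because a same-day emergency-contraception
query (gap 0) is the clinically salient case. Gap times are fractional
days; "within 24 hours" means a gap strictly below one day; medians use
lower interpolation on even counts (the reported value is always an
observed gap, never an average of two). Only the first query per class
per user enters the statistics, and second missed-OC episodes are not
re-anchored.

## Gestational dating

`infer_lmp()` implements `LMP = query date − 7 × reported week`. With
several pregnancy-week queries per user, the consensus LMP is the lower
median of the per-query dates, and the *consistency* of the inferences is
the median over all unordered pairs of absolute day differences, a
statistic robust to a single aberrant query. A pregnancy is *timed to the
index cycle* when `0 ≤ index date − consensus LMP < cycle length`
(28 days by default, configurable); for timed pregnancies the offset
itself is the conception-day estimate — the missed-dose date as the proxy
exposure day within the cycle, the only estimator computable from
observed fields alone. It naturally yields a dispersed distribution,
since it inherits both the true within-cycle variation and the dating
noise of the reported weeks.

## The censoring correction

A user who misses a pill in January and becomes pregnant can produce
pregnancy-week queries all the way to term inside the calendar-year
window; a user who misses a pill in December cannot. Ignoring this
right-censoring biases the pregnancy rate low. The correction follows
from the empirical week-of-pregnancy query distribution `p(k)`, estimated
as the fraction of *all* pregnancy-week queries in the log that mention
week *k* (using every pregnancy-week query, not only those of cohort
users, maximises the sample behind the weights). Each missed-OC user gets
an observability weight

```
w(index) = Σ_k p(k) · 1[index + 7k ≤ window end],
```

the probability that a pregnancy dated from the index would produce at
least one observable pregnancy-week query. A January user gets weight 1;
a December user a small weight. The weighted rate is

```
rate = (# users observed pregnant) / Σ_i w_i ,
```

a Horvitz–Thompson-style correction applied to the denominator only: an
observed pregnancy counts 1 regardless of its weight, matching the
operational definition of "pregnant" (issued at least one pregnancy-week
query after the index). A fully weighted variant is available behind
`both_sides = TRUE` for sensitivity analysis. Weights are floored at
`ε = 0.01` when used in the denominator so that a single very-late index
date cannot dominate; with the default week distribution the floor only
binds in the last four weeks of the window and shifts the rate by under
0.2% relative.

## What the synthetic generator encodes

The generator's defaults are the study conditions, not tuning knobs:

* **Cohort structure.** 50,000 users by default, one missed-OC query each,
  index dates uniform over calendar year 2018; dose-count mentions
  (67.1 / 21.4 / 6.3 / 3.4 / 1.8% for unspecified / 1 / 2 / 3 / 4+),
  pill-type mentions (60.8% none, 20.9% combined, 21.7% progestin-only,
  overlap implied), 10% placebo mentions; age from a two-component normal
  mixture solved for mean 32, SD 12, mode 20; a weak positive
  age–dose-count association via a Gaussian copula.
* **Pregnancy risk.** Per-user probabilities are assigned by mutually
  exclusive risk class with precedence placebo → progestin mention →
  2+ doses → base, and the two free class probabilities are *solved* so
  that the marginal rates of the measured strata equal the configured
  targets: 4.7% (non-placebo overall), 8.7% (progestin/minipill), 0.2%
  (placebo), 5.1% (2+ doses). Placebo mentions are drawn among users with
  no brand mention and fewer than two stated doses, which keeps the
  placebo stratum disjoint from the pill-type and multi-dose strata and
  the solved system feasible. The 30–34 age band carries a 2.1×
  pregnancy multiplier, normalised so the stratum targets stay marginal
  over age.
* **Gap times.** Each follow-up class draws its gap from a two-part
  mixture: a within-24h uniform component carrying the configured
  sub-day mass (37% EC, 20% abortion, 7% miscarriage) plus a log-normal
  (σ = 0.45) whose median is solved so the overall median equals the
  configured class median (11, 28, 35 days). A single log-normal cannot
  carry both summaries for the EC class without σ ≈ 7, which would put a
  third of its mass beyond one year and let window truncation drag the
  observed median below one day; the mixture keeps the beyond-window
  mass negligible so the observed statistics sit close to the configured
  ones.
* **Pregnancy queries and censoring.** A pregnant user's queries cluster
  at an anchor gestational week drawn from a triangular pmf (support
  weeks 4–24, peak 8); dates are `LMP + 7k + t` with `t` uniform on
  ±3 days, and the reported week is `k` plus a ±1 error with
  `P(0) = 0.695`. These two noise parameters were calibrated jointly, by
  enumeration of the pairwise error distribution, so that the cohort
  median pairwise difference between inferred LMPs is 4 days. Queries
  dated beyond the window end are silently lost — that is the censoring
  mechanism the weights undo. 19% of pregnancies are *timed*
  (LMP = index − conception offset, the offset a truncated normal with
  mean 14.4, SD 7.2 on [0, 28)); the rest are placed one or two cycles
  *before* the index cycle, with their anchor week shifted forward by the
  corresponding whole weeks so their queries still fall after the index.
  This placement reflects pregnancies conceived in earlier cycles under
  imperfect OC use and discovered later; a small whole-day nudge on the
  two-cycle branch balances the first-query date against the
  `index + 7k` threshold the weight formula assumes, which is what makes
  the weighted estimator mean-unbiased under the generator (verified by
  the 200-replicate calibration test).
* **Background users.** Two background pregnancy-week-only users per
  cohort user, with LMPs uniform over an interval wide enough that every
  gestational week is equally likely to fall inside the window. Their
  observed reported weeks are then an unbiased draw from the configured
  week pmf (convolved with the reporting-error kernel), which stabilises
  the estimated week distribution against the low-week skew of the
  censored cohort queries. Real logs supply this dilution for free —
  most pregnancy-week queries come from users who never queried about a
  missed pill.

The generator writes a per-user ground-truth sidecar (pregnancy
indicator, true LMP and conception date, subgroup labels, censoring
indicator) that `recover_report()` compares against pipeline estimates.

## Numerical choices and degenerate inputs

* Dates are compared at day resolution except gap times (fractional
  days); timestamps are ISO-8601 UTC.
* Lower-interpolated medians for gap times and the consensus LMP;
  standard medians for consistency values, which may be half-integers.
* Ties in timestamps are broken by stable input order.
* Empty-text and out-of-window records are dropped with a reported
  count; a report generated from a log with more than 10% exclusions
  carries a warning flag.
* An empty follow-up class yields an explicit empty result, not an
  error; a log with no pregnancy-week queries cannot support weights and
  says so; Cohen's kappa reports 0 by convention when both raters are
  constant and concordant; an all-tied Spearman input reports an absent
  correlation.
* Subgroup tables flag strata under 50 users rather than suppressing
  them.

## What the tests do and do not show

The test suite validates the *estimators* under the generator's
assumptions: unbiased recovery of stratum rates (including a
200-replicate calibration of the weighted estimator at n = 5,000),
gap-time and gestational statistics within Monte-Carlo tolerance at
n = 50,000, exact agreement of the weights with brute-force enumeration,
and exact LMP inversion when reporting noise is switched off. The
generator does not model misspelled or ambiguous query text,
non-protagonist queries ("my sister missed her pill"), multiple
missed-OC episodes per user, or pregnancy outcomes; passing tests
therefore say nothing about classifier precision on real text — on real
logs the keyword rules are known to admit irrelevant queries (quantify
with `cohens_kappa()` on a manual relevance review) — and nothing about
whether the timed-pregnancy definition captures true conception cycles
in the real population. The untimed-pregnancy placement is one of
several mechanisms consistent with the observable statistics; analyses
that depend on *where* untimed pregnancies truly fall relative to the
index should treat that component as a modelling convention.

Problem sizes in the shipped tests — 50,000 users for the single-cohort
recovery checks, 200 replicates of 5,000 users for calibration — keep
every subgroup above a few hundred users while the full suite runs in a
few minutes on one core.

## Limitations

Weights are computed from the same censored log they correct, so the
estimated week distribution is itself slightly censored; the background
dilution bounds this contamination but a log consisting only of cohort
users would inherit it in full. The weight formula dates observability
from the index query, not from the (unobserved) true LMP; the generator
quantifies the residual bias of that approximation and keeps it within
Monte-Carlo noise, but other cohort structures could widen it. Variance
estimates for the weighted rate are provided only via the percentile
bootstrap (`bootstrap_rate_ci()`); no closed-form theory is attempted.
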