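# ocquery

Search-engine query-log analysis of missed oral-contraceptive (OC) doses.

People who miss a birth-control pill often turn to a search engine before
(or instead of) a clinician. Their anonymized query streams — "forgot my
birth control pill", then perhaps "plan b near me", and months later
"pregnancy week 8 symptoms" — make the downstream consequences of a missed
dose measurable at population scale. `ocquery` is an infodemiology toolkit
for exactly this design:

* **Rule-based classification** of queries into five classes: missed OC
  dose, miscarriage, abortion, emergency contraception, and
  pregnancy-week queries, driven by an editable keyword/brand lexicon.
* **Timeline linkage**: per-user timelines anchored at the first missed-OC
  (index) query, with incidence and gap-time statistics for each
  follow-up class.
* **Gestational dating**: each "week *k* of pregnancy" query implies
  LMP = query date − 7*k*; recurrent queries give a consensus LMP, a
  consistency score, and a *timed-to-cycle* classification with a
  conception-day estimate.
* **Right-censoring correction**: with a finite observation window, a
  December missed-pill user cannot be observed pregnant the way a January
  user can. Each user receives an observability weight

      w(index) = Σ_k p(k) · 1[index + 7k ≤ window end]

  from the empirical week-of-pregnancy query distribution p(k), and the
  corrected pregnancy rate is
  `(# users observed pregnant) / Σ w_i` — overall and within subgroups
  (pill type, placebo mention, ≥2 missed doses).
* **Cohort statistics**: age-band follow-up ratios with chi-square tests,
  age–dose Spearman correlation, dose/pill tabulations, and a Cohen's
  kappa utility for labeler-agreement checks.
* **A synthetic query-log generator** with a ground-truth sidecar, so that
  every estimator is validated by parameter recovery under known
  conditions (real logs of this kind are proprietary).

See the methods vignette (`vignettes/weighted-pregnancy-rates.Rmd`) for
the model, its assumptions, and the design decisions.

## Worked example

```r
library(ocquery)

cfg <- scenario_config(n_users = 5000)   # one-year window, defaults
sim <- generate_cohort(cfg, seed = 7)    # query log + ground truth
head(sim$log[, c("user_id", "timestamp", "text")], 3)
#>   user_id timestamp           text
#> 1 b009473 2018-01-01 00:12:42 what to expect on week 14 of pregnancy
#> 2 b004617 2018-01-01 00:18:56 week 11 of pregnancy what is happening
#> 3 b000001 2018-01-01 00:20:14 what to expect on week 10 of pregnancy

rep <- analyze_cohort(sim$log)
rep
#> <oc_report>
#>   17860 records -> 5000 cohort users
#>   pregnancy rate: weighted 4.24% (unweighted 3.28%), 164 pregnant / 5000 users
#>   timed 16.5%, conception day 14.8 (SD 5.5), LMP consistency 5.0 d
```

The weighted rate (4.24%) sits above the raw rate (3.28%) because users
who missed a pill late in the year could not be observed pregnant; the
weights shrink the denominator to the observable-equivalent cohort size.
At this sample size the estimate is within Monte-Carlo noise of the
generator's configured 4.7% non-placebo rate (at the default n = 50,000
it recovers it within three standard errors; see the acceptance tests).

```r
as.data.frame(rep$followups)
#>                     class n_users_with_followup fraction_of_missed_users median_gap_days fraction_within_24h n_before_pregnancy
#> 1             miscarriage                   196                   0.0392            33.3              0.0561                  6
#> 2                abortion                   300                   0.0600            25.4              0.2467                 12
#> 3 emergency_contraception                   647                   0.1294            10.7              0.3879                 26
#> 4          pregnancy_week                   164                   0.0328            70.9              0.0000                  0

rep$rates$pill_type
#>          stratum n_users n_pregnant effective_n weighted_rate unweighted_rate
#> 1       combined    1065         35         810        0.0432          0.0329
#> 2 progestin_only    1077         72         849        0.0848          0.0669
#> 3    unspecified    3022         67        2339        0.0286          0.0222
```

Half of emergency-contraception follow-ups arrive days after the missed
pill (median 10.7 days, only 39% within 24 hours), and the
progestin-only/minipill stratum carries roughly double the pregnancy rate
of the combined-pill stratum — the patterns the pipeline is built to
quantify.

File-based workflows mirror the same steps
(`simulate_to_files()`, `read_query_log()`, `write_report()`,
`recover_report()`), and a thin command-line wrapper is installed at
`inst/cli/ocquery`:

```sh
Rscript inst/cli/ocquery simulate --out-log log.tsv --out-truth truth.tsv --n-users 5000 --seed 7
Rscript inst/cli/ocquery analyze  --log log.tsv --out report.json
Rscript inst/cli/ocquery recover  --log log.tsv --truth truth.tsv --out recovery.tsv
```

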