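# bqscreen

Questionnaire-based screening for obstructive sleep apnea (OSA) risk, built
around the Berlin Questionnaire (BQ), for biostatisticians and survey
methodologists who need the full pipeline — deterministic scoring, group
statistics, per-item discrimination scores, and machine-learning item
reduction — as tested, reusable R functions.

OSA is heavily underdiagnosed; the BQ is the most widely used paper
screening instrument for it. Its ten items form three categories — snoring
(B1–B5), daytime somnolence (B6–B8), and hypertension/obesity (B10 + BMI) —
and a subject is **high risk** when ≥ 2 categories are positive (a category
is positive with ≥ 2 frequent-symptom answers, or, for category 3, with a
hypertension history or BMI > 30 kg/m²). Because no individual-level survey
data is deposited for the study this package operationalizes, a calibrated
synthetic-cohort generator reproduces the published class-conditional
response tables of its 311 low-risk / 76 high-risk respondents, with labels
always recomputed by the scorer.

The analysis core:

* **Per-item discrimination.** Fisher score
  `F = (x̄₁ − x̄₂)² / (σ₁² + σ₂²)` (population variances) and rank AUROC
  `= (#{high > low} + ½·ties) / (n₁n₂)`, computable in closed form from
  grouped counts (`bq_grouped_scores()`), identically to expanding the
  counts into individuals.
* **Voted backward feature selection.** A 70/30 selection/assessment split;
  each elimination step repeats a one-feature backward pass R times on
  reshuffled data with a reseeded gradient-boosted-tree scorer (xgboost,
  native missing-value handling), downvoting the feature whose removal
  costs least; the most-downvoted feature is removed. Surviving subsets are
  scored on the held-out part by repeated refits, giving an AUROC-vs-
  cardinality curve; the whole procedure repeats over many splits to
  measure how stable the small "best" subsets are (`bq_run_protocol()`,
  `bq_aggregate_runs()`, `bq_cooccurrence()`, `bq_cv_auroc()`).

See `vignettes/bq-screening-methods.Rmd` for the full methods account.

## Worked example

```r
library(bqscreen)

## discrimination scores of the hypertension item from published grouped counts
b10 <- bq_xtab_from_conditional(bq_default_conditionals()$B10)
bq_grouped_scores(b10)
#> <bq_discrim> B10: AUROC = 0.744, F = 0.798 (n = 300 low / 72 high)

## a synthetic cohort at the study's size; labels recomputed by the scorer
coh <- bq_generate_cohort(bq_generator_config(n_subjects = 387, seed = 1))
table(attr(coh, "label"))
#>  low high
#>  313   74

enc <- bq_encode(coh)
head(bq_score_all(enc), 4)
#>    item_id auroc fisher_f n_low n_high
#> 1       B1 0.837    1.918   231     72
#> 3       B3 0.822    1.032   313     74
#> 6       B6 0.797    0.827   313     74
#> 10     B10 0.766    1.018   300     69

## voted backward selection over 10 dataset splits (desk-scale settings)
cfg <- bq_protocol_config(inner_reps = 20, eval_reps = 10, outer_runs = 10,
                          seed = 1, classifier = bq_classifier_xgb(nrounds = 30))
bq_aggregate_runs(enc, cfg)
#> <bq_run_aggregate> size-3 subsets over 10 runs
#> selection frequency:
#> B10  B6  B2  B1  B7  B3 BMI  B4  B5  B8  B9
#> 0.9 0.8 0.6 0.3 0.2 0.1 0.1 0.0 0.0 0.0 0.0

cv <- bq_cv_auroc(enc, c("B1", "B6", "B10"), cfg)
sprintf("CV AUROC {B1,B6,B10}: %.3f (SD %.3f)", cv$mean, cv$sd)
#> "CV AUROC {B1,B6,B10}: 0.945 (SD 0.004)"
```

Reading the output: the grouped closed form reproduces the published
discrimination pair of the hypertension item (AUROC 0.74, F 0.80); the
synthetic cohort's recomputed high-risk rate lands near the study's 20%
without tuning; snoring items dominate the univariate ranking; and across
splits the hypertension item is the most consistently selected member of
the 3-item reduced questionnaire, whose cross-validated AUROC against the
full-BQ outcome stays well above 0.9. (On the real, more internally
consistent respondents the reported 3-item AUROC was higher still; the
generator's within-class independence is a documented limitation.)

A thin CLI over the same functions is installed at `inst/cli/bq`
(`simulate`, `score`, `summarize`, `discrim`, `select`, `cv`, `report`),
writing a JSON manifest next to every output.

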