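---
title: "Methods: Berlin Questionnaire scoring, synthetic cohorts, and voted backward feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Berlin Questionnaire scoring, synthetic cohorts, and voted backward feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the scoring model and
its assumptions, the synthetic-data generator and what it does and does not
emulate, the statistical conventions, the feature-selection protocol, and the
numerical choices made where the design was genuinely open.

## The instrument and the risk label

The Berlin Questionnaire (BQ) screens for obstructive sleep apnea (OSA) risk
with ten items in three categories: snoring behaviour (B1–B5), daytime
somnolence (B6–B8), and hypertension/obesity (B10 plus BMI). Two items are
skip-logic follow-ups: B2 (snoring loudness) follows B1, and B9 (frequency of
nodding off while driving) follows B8; B9 does not itself enter category
scoring.

A response counts as a *positive symptom* when it indicates frequent
symptoms. `bq_item_dictionary()` encodes the rule: `Yes` for the yes/no items
(B1, B4, B8, B10), the two loudest levels for B2, "3-4 times a week" or
"Every day" for the frequency items B3, B6, B7, and additionally "1-2 times a
week" for the breathing-pause item B5. These positive sets are stored per
item and are deliberately *suffixes* of the printed ordinal level order: that
upward closure is what makes the label monotone — escalating any single
answer, or raising BMI, can never turn a high-risk subject into a low-risk
one. The test suite asserts this property on random records.

Category 1 is positive with at least two positive answers among B1–B5,
category 2 with at least two among B6–B8, and category 3 when B10 is `Yes`
or BMI > 30 kg/m². The subject is **high risk** when two or more categories
are positive. Missing answers are simply unavailable: they never count as
positive, and a category is evaluated from whatever was answered. Whether the
original study scored or dropped partially missing respondents is not
documented; scoring from available items is the weaker assumption and keeps
every record usable.

"Do not know" is never a positive symptom response. For *numeric encoding*
(`bq_encode()`) every level takes its 0-based index in the instrument-printed
order, and two policies govern "Do not know": `as_missing` (default) maps it
to the missing marker `NA`; `as_middle` keeps its ordinal position, which in
the printed No / Do not know / Yes order is literally the middle code. The
default is the convention under which the closed-form discrimination scores
of the hypertension item reproduce their published values (below);
`as_middle` is retained for sensitivity analysis.

## Synthetic cohorts

No individual-level survey data is deposited, so analyses run on synthetic
cohorts calibrated to the published class-conditional tables
(`bq_default_conditionals()`): for each item, the response counts in the
low-risk (n = 311) and high-risk (n = 76) groups. `bq_generate_cohort()`
draws, per subject, a latent class (Bernoulli, default prevalence 0.20, the
study's high-risk proportion), then each item from its class-conditional
distribution, missing mass included. BMI is drawn by sampling the BMI group
(underweight / normal / overweight / obese, as published) and then uniformly
within the group's range, with the top group capped at the published maximum
of 46 kg/m²; the BMI-group column is re-derived from the drawn value so the
two never disagree.

Design choices worth stating explicitly:

* **The analysis label is recomputed, not copied.** The published target
  variable is the BQ outcome itself, a deterministic function of the
  answers. The generator therefore discards the latent class for analysis
  purposes (it is kept as a diagnostic attribute) and labels every subject
  with `bq_classify_risk()`. Under the default calibration the recomputed
  prevalence comes out near the study's 20% without any tuning, which is a
  useful internal consistency check of the transcribed tables, and the
  recomputed label associates strongly with the latent class (odds ratio
  far above 1 in the test suite).
* **Independence within class.** Only class-conditional marginals are
  published, so items are sampled independently given the class. Real
  respondents are more internally consistent (a heavy snorer answers several
  snoring items positively at once), so real data carries more redundancy
  across items than the synthetic cohorts do. Consequences: discrimination
  scores and selection behaviour are qualitatively comparable, but small
  item subsets retain slightly *less* of the full questionnaire's
  information here than was reported on the real cohort. Passing tests on
  synthetic cohorts demonstrate the pipeline's correctness and the
  robustness mechanics, not the clinical performance figures.
* **Skip logic.** With `skip_logic = TRUE` (default), B1 = "No" forces B2 to
  be structurally missing, and B9 is sampled from its full conditional only
  when B8 = "Yes", otherwise restricted to "Never or almost never" or
  missing. The published tables themselves are *not* strictly skip-
  consistent (more subjects deny snoring than have B2 missing), so enforcing
  consistency necessarily moves the follow-up items' missingness away from
  the printed missing rows; the answered-level distributions, conditional on
  eligibility, match the tables exactly and that is what the calibration
  tests check (goodness of fit on a 20,000-subject cohort, per item, within
  each latent class).
* **Transcription fidelity.** Four published cells are internally
  inconsistent (two columns that do not sum to their group size, one count
  printed only as a percentage, one garbled cell). They are transcribed as
  printed, flagged in the `flags` field of the affected tables, and left
  unrepaired.

## Group statistics

`bq_crosstab()` tabulates levels by recomputed label, tracking missing
answers separately. Percentages are taken of the full class total with
missing shown as its own row, matching the published layout, and displayed
with half-up integer rounding (base R's round-half-even would break several
printed values). The original analysis names its tests but not their mapping
to tables, so routing is fixed deterministically: Pearson chi-square without
continuity correction by default; Fisher's exact test when the table is 2x2
and any expected cell is below 5; Mann-Whitney (normal approximation with
tie correction) reported alongside for ordinal items, Kruskal-Wallis when
more than two groups are requested. No multiple-testing correction is
applied, as none was applied in the source analysis. The reported
Mann-Whitney statistic is the pair-count form, so dividing it by
`n1 * n2` gives exactly the rank AUROC of the same data — an identity the
test suite asserts against `wilcox.test()`.

## Single-variable discrimination

Two complementary indices per item, both computed after removing missing
values under the chosen policy:

* Fisher score `F = (x̄_low − x̄_high)² / (σ²_low + σ²_high)`, with
  population (divide-by-n) variances;
* rank AUROC `= (#{high > low pairs} + ½·ties) / (n_low·n_high)`, with the
  orientation fixed by the coding direction and never auto-flipped —
  reproducibility is preferred over cosmetic symmetry, and a value below 0.5
  is a signal of reversed coding, not an error.

`bq_grouped_scores()` evaluates both in closed form from a level × class
contingency table; an oracle test checks it is *identical* to expanding the
counts into individuals. Under the default convention (codes in printed
order, "Do not know" as missing, population variances) the hypertension item
B10 computed from its published counts gives AUROC 0.74 and F 0.80, exactly
the values reported for it. The same closed form applied to the published B1
counts does **not** reproduce that item's reported pair (0.88 / 1.9) under
any tested convention (it gives ≈0.85/2.10 with DK-as-missing, ≈0.87/2.05
with DK-as-middle); the reported B1 values were plausibly obtained from the
classifier on the raw data rather than from the grouped counts, and the
package makes no attempt to force agreement.

## The voted backward selection protocol

The protocol measures what small item subsets can reproduce the full BQ
outcome. It never re-implements the boosting algorithm: the scorer is a
contract (`fit`/`score`, native missing-value handling, seedable), defaulting
to gradient-boosted trees via xgboost — 100 rounds, depth 3, learning rate
0.1, row subsampling 0.8, single-threaded histogram growth. Subsampling is
what makes "reseed and refit" repetitions genuinely vary on fixed data;
single-threading plus a fixed seed makes every fit reproducible. A
deterministic stub classifier is provided for oracle tests of the protocol
mechanics.

One run (`bq_run_protocol()`):

1. **Split** the encoded data once into P1 (selection, 70%) and P2
   (assessment, 30%), stratified by label — at 20% prevalence unstratified
   splits too easily starve a part of high-risk subjects. `|P1|` is exactly
   `floor(0.7·N)` via largest-remainder allocation (387 subjects → 270/117).
2. **Eliminate one feature per step**, the step decided by voting
   (`bq_downvote_round()`): the elimination is repeated R = 100 times; each
   repetition redraws a stratified internal 70/30 holdout of P1 from the
   shuffled row order and reseeds the classifier, scores every candidate by
   the holdout AUROC of the model fitted *without* it, and downvotes the
   candidate whose absence hurts least. The feature with the most downvotes
   is removed; ties break toward earlier questionnaire item order for
   determinism. The per-repetition holdout is the package's choice for the
   unstated inner criterion: the shuffle is then exactly what drives
   vote-to-vote variability, and one fit per candidate (instead of an inner
   cross-validation per candidate) keeps the voted protocol tractable —
   the voting average is the robustness mechanism either way.
3. **Score every surviving subset on P2** (`bq_evaluate_subset()`): 50
   refit-with-new-seed repetitions, reporting mean AUROC ± SD. This yields
   the AUROC-vs-cardinality curve, one point per cardinality from the full
   set down to a single feature, and the removal order (least predictive
   first).

`bq_aggregate_runs()` repeats the whole procedure over fresh P1/P2 splits
(default 60) and reports how often each feature appears in the size-3
surviving subsets — the headline cardinality, at which the published
analysis found predictive power comparable to the whole questionnaire.
`bq_cooccurrence()` counts unordered feature pairs across those best
subsets; the published normalization constant is not recoverable from the
printed matrix, so the package normalizes by the total pair count (upper
triangle sums to 1) and records the constant. `bq_cv_auroc()` evaluates a
candidate reduced questionnaire on the whole dataset with repeated
stratified 5-fold cross-validation, pooling out-of-fold scores within each
repetition.

On synthetic cohorts the protocol reliably ranks the hypertension item B10
at the top of the selection frequencies, mirrors the reported 3-item
plateau of the AUROC curve, and recovers a planted label-defining feature
from noise — these are the properties the acceptance tests assert. One
synthetic-data effect deserves a note: B2's structural missingness is
informative (it encodes B1 = "No"), and the sparsity-aware splits exploit
it, so B2 can appear in best subsets more often than its answered values
alone would warrant. The same mechanism exists in the real instrument.

## Problem sizes and numerical choices

* Test-suite and example runs use desk-scale protocol sizes chosen as the
  package's own defaults for quick reproduction: R = 20 downvoting
  repetitions, 10 evaluation repetitions, 10 outer runs, 30 boosting rounds,
  cohorts of n = 387 (the study size) and n = 20,000 for generator
  calibration. The full-scale defaults (100 / 50 / 60 runs, 100 rounds)
  remain the function defaults.
* All randomness flows from explicit integer seeds; child seeds are derived
  with `sample.int` under a temporarily-set seed, keeping every seed below
  2³¹. A run of the full protocol is byte-reproducible given the dataset
  and one seed.
* Display rounding is half-up (`round_half_up()`); raw values are always
  retained alongside.
* Degenerate inputs have defined behaviour: a single-level table scores
  AUROC 0.5 and F 0; zero total variance with distinct means reports `Inf`;
  empty classes, empty cohorts and non-2x2 Fisher inputs are errors; a split
  that loses a class is redrawn with the next seed and a warning.

## Limitations

The label is the BQ outcome, not an OSA diagnosis; nothing here validates
the questionnaire against polysomnography. Within-class independence
understates inter-item redundancy (see above). The generator reproduces
class-conditional marginals, not joint demographics. The four flagged
transcription inconsistencies are carried as printed. Percentages, tests and
scores computed from the published grouped counts inherit any rounding in
those counts.
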