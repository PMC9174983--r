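Package: bqscreen
Title: Berlin Questionnaire Scoring, Cohort Simulation, and
    Machine-Learning Item Reduction for Sleep Apnea Risk Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for questionnaire-based obstructive sleep apnea (OSA)
    risk screening built around the Berlin Questionnaire (BQ): a
    deterministic implementation of the three-category BQ scoring rule; a
    synthetic survey-cohort generator calibrated to published
    class-conditional response tables; descriptive and inferential group
    comparisons (chi-square, Fisher exact, rank tests); single-variable
    discrimination scores (Fisher score and rank-based AUROC, computable
    in closed form from grouped counts); and a robustness-voted backward
    sequential feature-selection protocol with gradient-boosted-tree
    scoring that reduces the ten-item instrument to a short subset with
    comparable predictive power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
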