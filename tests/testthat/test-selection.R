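# Protocol mechanics are exercised with the deterministic stub classifier;
# learning behaviour with the boosted backend is covered by the planted and
# synthetic-cohort acceptance checks.

stub_cfg <- function(col = "signal", ...) {
  bq_protocol_config(classifier = stub_on(col), ...)
}

test_that("split gives floor(0.7 N) stratified rows, deterministically", {
  enc <- planted_dataset(n = 387, seed = 2)
  sp <- bq_split_dataset(enc, 0.7, seed = 5)
  expect_equal(nrow(sp$P1$x), 270)
  expect_equal(nrow(sp$P2$x), 117)
  expect_equal(sum(sp$P1$labels == "high") + sum(sp$P2$labels == "high"),
               sum(enc$labels == "high"))
  # stratification keeps the class ratio in both parts
  expect_lt(abs(mean(sp$P1$labels == "high") - mean(enc$labels == "high")), 0.02)
  sp2 <- bq_split_dataset(enc, 0.7, seed = 5)
  expect_identical(sp$P1$x, sp2$P1$x)
  expect_error(bq_split_dataset(planted_dataset(n = 6), 0.7), "too small")
  expect_error(bq_protocol_config(train_frac = 1), "train_frac")
})

test_that("downvoting removes the least informative feature", {
  enc <- planted_dataset(n = 200, n_noise = 1, seed = 3)
  cfg <- stub_cfg(inner_reps = 20, seed = 1)
  step <- bq_downvote_round(enc, c("signal", "noise1"), cfg)
  # scoring without noise1 keeps the stub's signal column: noise1 is
  # downvoted in every repetition
  expect_equal(unname(step$tally["noise1"]), 20L)
  expect_equal(step$removed, "noise1")
  one <- bq_downvote_round(enc, c("signal", "noise1"),
                           stub_cfg(inner_reps = 1, seed = 1))
  expect_equal(sum(one$tally), 1L)  # one-hot tally at R = 1
  expect_error(bq_downvote_round(enc, "signal", cfg), "at least 2")
})

test_that("downvote ties break toward earlier feature order", {
  enc <- planted_dataset(n = 100, n_noise = 2, seed = 4)
  # constant scorer: every candidate scores identically
  cfg <- bq_protocol_config(
    classifier = bq_classifier_stub(function(x) rep(0.5, nrow(x))),
    inner_reps = 5, seed = 1)
  step <- bq_downvote_round(enc, c("noise1", "noise2"), cfg)
  expect_equal(step$removed, "noise1")
  expect_equal(unname(step$tally["noise1"]), 5L)
})

test_that("subset evaluation equals the rank AUROC of the stub's scores", {
  enc <- planted_dataset(n = 150, seed = 6)
  sp <- bq_split_dataset(enc, 0.7, seed = 1)
  cfg <- stub_cfg(eval_reps = 1, seed = 9)
  ev <- bq_evaluate_subset(sp$P1, sp$P2, c("signal", "noise1"), cfg)
  scores <- sp$P2$x[, "signal"]
  expect_equal(ev$mean, bq_rank_auroc(scores[sp$P2$labels == "low"],
                                      scores[sp$P2$labels == "high"]))
  expect_equal(ev$sd, 0)
  # a label-defining feature scores perfectly with zero spread
  ev2 <- bq_evaluate_subset(sp$P1, sp$P2, "signal", stub_cfg(eval_reps = 10))
  expect_equal(ev2$mean, 1)
  expect_equal(ev2$sd, 0)
})

test_that("the protocol emits one curve point per cardinality and a full removal order", {
  enc <- planted_dataset(n = 120, n_noise = 4, seed = 8)
  cfg <- stub_cfg(inner_reps = 3, eval_reps = 2, seed = 11)
  tr <- bq_run_protocol(enc, cfg)
  expect_equal(tr$curve$cardinality, 5:1)
  expect_false(any(is.na(tr$curve$mean_auroc)))
  expect_setequal(tr$removal_order, enc$features)
  expect_equal(length(tr$steps), 4)
  # the stub can only see the signal column: it survives to the end
  expect_equal(tr$removal_order[5], "signal")
  expect_identical(tr$curve, bq_run_protocol(enc, cfg)$curve)
  expect_setequal(bq_best_subset(tr, 2), tail(tr$removal_order, 2))
})

test_that("aggregation reports 0/1 frequencies for a single run", {
  enc <- planted_dataset(n = 120, n_noise = 3, seed = 14)
  agg <- bq_aggregate_runs(enc, stub_cfg(inner_reps = 3, eval_reps = 2,
                                         outer_runs = 1, subset_size = 2, seed = 3))
  expect_length(agg$best_subsets, 1)
  expect_true(all(agg$frequency %in% c(0, 1)))
  expect_equal(unname(agg$frequency["signal"]), 1)
})

test_that("co-occurrence counts unordered pairs and normalizes to one", {
  m <- bq_cooccurrence(list(c("A", "B"), c("A", "B"), c("A", "C")))
  expect_equal(m["A", "B"], 2 / 3)
  expect_equal(m["A", "C"], 1 / 3)
  expect_equal(m["B", "C"], 0)
  expect_equal(m, t(m))
  expect_equal(sum(m[upper.tri(m)]), 1)
  single <- bq_cooccurrence(list(c("A", "B")))
  expect_equal(single["A", "B"], 1)
  expect_warning(empty <- bq_cooccurrence(list("A", "B")), "singleton")
  expect_equal(sum(empty), 0)
})

test_that("repeated stratified CV scores subsets on out-of-fold data", {
  enc <- planted_dataset(n = 200, seed = 16)
  cv <- bq_cv_auroc(enc, "signal", stub_cfg(eval_reps = 5, cv_folds = 5, seed = 2))
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)
  # pure-noise features score near chance
  set.seed(17)
  null_enc <- bq_encoded(matrix(rnorm(2000), 1000, 2),
                         rep(c("low", "high"), c(800, 200)))
  cv0 <- bq_cv_auroc(null_enc, "f1",
                     bq_protocol_config(classifier = stub_on("f1"),
                                        eval_reps = 5, seed = 4))
  expect_lt(abs(cv0$mean - 0.5), 0.05)
})

test_that("the boosted backend plugs into the protocol end to end", {
  enc <- planted_dataset(n = 150, n_noise = 2, seed = 19)
  cfg <- bq_protocol_config(inner_reps = 2, eval_reps = 2, seed = 7,
                            classifier = bq_classifier_xgb(nrounds = 10))
  tr <- bq_run_protocol(enc, cfg)
  expect_equal(tr$removal_order[3], "signal")
  expect_gt(tr$curve$mean_auroc[tr$curve$cardinality == 1], 0.95)
  expect_identical(bq_run_protocol(enc, cfg)$curve, tr$curve)
})
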