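test_that("crosstab counts levels by recomputed label and tracks missing", {
  low <- make_record()
  high <- make_record(B1 = "Yes", B4 = "Yes", B10 = "Yes")  # cat1 + cat3
  coh <- rbind(low, low, high)
  xt <- bq_crosstab(coh, "B1")
  expect_equal(unname(xt$counts[, "high"]), c(0, 0, 1))
  expect_equal(unname(xt$counts[, "low"]), c(2, 0, 0))
  miss <- rbind(coh, make_record(B1 = NA))
  xt2 <- bq_crosstab(miss, "B1")
  expect_equal(unname(xt2$missing["low"]), 1L)
  expect_error(bq_crosstab(coh[0, ], "B1"), "empty")
  expect_error(bq_crosstab(coh, "B99"), "unknown")
})

test_that("group percentages reproduce published narrative values", {
  cond <- bq_default_conditionals()
  pc <- function(id) bq_group_percentages(bq_xtab_from_conditional(cond[[id]]))
  b1 <- pc("B1")
  expect_equal(b1$pct_high[b1$level == "Yes"], 95)
  expect_equal(b1$pct_low[b1$level == "Yes"], 21)
  b3 <- pc("B3")
  expect_equal(b3$pct_high[b3$level == "Every day"], 63)
  b10 <- pc("B10")
  expect_equal(b10$pct_high[b10$level == "Yes"], 51)
  expect_equal(b10$pct_low[b10$level == "Yes"], 5)
  # all-mass level
  one <- bq_group_percentages(bq_xtab("x", c("a", "b"), c(9, 0), c(4, 0)))
  expect_equal(one$pct_low[1], 100)
})

test_that("raw percentages per class sum to 100 including the missing row", {
  cond <- bq_default_conditionals()
  for (id in c("B2", "B9", "B10")) {
    p <- bq_group_percentages(bq_xtab_from_conditional(cond[[id]]))
    expect_equal(sum(p$pct_low_raw), 100, tolerance = 1e-10)
    expect_equal(sum(p$pct_high_raw), 100, tolerance = 1e-10)
  }
})

test_that("chi-square matches hand computations and is permutation-invariant", {
  even <- bq_chisq_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  diag <- bq_chisq_test(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag$statistic, 40)
  expect_equal(diag$dof, 1L)
  m <- matrix(c(30, 12, 7, 25, 3, 18), 3)
  perm <- m[c(2, 3, 1), c(2, 1)]
  expect_equal(bq_chisq_test(m)$statistic, bq_chisq_test(perm)$statistic)
  # published hypertension table is strongly significant
  b10 <- bq_xtab_from_conditional(bq_default_conditionals()$B10)
  expect_lt(bq_chisq_test(b10)$p_value, 0.001)
  expect_error(bq_chisq_test(matrix(c(5, 0, 7, 0), 2)), "degenerate")
})

test_that("Fisher exact test matches the hypergeometric hand values", {
  expect_equal(bq_fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(bq_fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  # stroke/TIA item: rare-event 2x2
  q15 <- bq_xtab_from_conditional(bq_default_conditionals()$Q15)
  expect_lt(bq_fisher_exact(q15)$p_value, 0.01)
  expect_error(bq_fisher_exact(matrix(1:6, 3)), "2x2")
  # collapsing levels first
  xt <- bq_xtab("x", c("a", "b", "c"), c(10, 5, 5), c(2, 8, 8))
  expect_equal(bq_fisher_exact(xt, collapse = "a")$p_value,
               fisher.test(matrix(c(10, 10, 2, 16), 2, byrow = TRUE))$p.value)
})

test_that("rank test reports the Mann-Whitney U with the AUROC identity", {
  coh <- rbind(make_record(B3 = "Never or almost never"),
               make_record(B3 = "Never or almost never"),
               make_record(B3 = "Never or almost never"),
               make_record(B3 = "1-2 times a week"),
               make_record(B3 = "1-2 times a week"),
               make_record(B3 = "1-2 times a week"))
  grp <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  res <- bq_rank_test(coh, "B3", groups = grp)
  expect_equal(res$test_name, "mann_whitney")
  expect_equal(res$statistic, 9)  # all pairs concordant
  coh4 <- coh[c(1, 4, 2, 5), ]
  same <- bq_rank_test(coh4, "B3", groups = factor(c("low", "low", "high", "high"),
                                                   levels = c("low", "high")))
  expect_equal(same$statistic, 2)  # n1*n2/2 under identical samples
  expect_gt(same$p_value, 0.99)
  kw <- bq_rank_test(coh, "B3", groups = factor(c(1, 1, 2, 2, 3, 3)))
  expect_equal(kw$test_name, "kruskal_wallis")
  expect_error(bq_rank_test(coh, "B3", groups = factor(rep("low", 6),
                                                       levels = c("low", "high"))),
               "empty")
})

test_that("the ordinal B3 shift is detected on generated cohorts", {
  coh <- bq_generate_cohort(bq_generator_config(n_subjects = 387, seed = 12))
  expect_lt(bq_rank_test(coh, "B3")$p_value, 0.05)
})

test_that("summary table assembles counts, tests and significance stars", {
  coh <- bq_generate_cohort(bq_generator_config(n_subjects = 387, seed = 8))
  tab <- bq_summary_table(coh, items = c("B1", "B3", "B8"))
  expect_setequal(unique(tab$item_id), c("B1", "B3", "B8"))
  first <- tab[tab$test != "", ]
  expect_equal(nrow(first), 3)
  expect_true(all(first$stars[first$p_value < 0.001] == "***"))
  expect_true(all(tab$stars[!is.na(tab$p_value) & tab$p_value >= 0.05] == ""))
  # star thresholds
  p <- c(0.0005, 0.005, 0.03, 0.5)
  stars <- bqscreen:::significance_stars(p)
  expect_equal(stars, c("***", "**", "*", ""))
})
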