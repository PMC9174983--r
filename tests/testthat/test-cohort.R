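test_that("default conditionals carry the published counts", {
  cond <- bq_default_conditionals()
  b10 <- cond$B10
  expect_equal(unname(b10$counts_low[c("No", "Yes", "Do not know")]),
               c(284, 16, 11))
  expect_equal(unname(b10$counts_high[c("No", "Yes", "Do not know")]),
               c(33, 39, 4))
  expect_equal(unname(cond$B1$counts_low[c("No", "Yes", "Do not know")]),
               c(164, 64, 83))
  expect_equal(sum(cond$B5$counts_high), 76)
  # structural missingness of the follow-up items
  expect_equal(cond$B2$missing_low, 74L)
  expect_equal(cond$B2$missing_high, 0L)
  expect_equal(cond$B9$missing_low, 78L)
  expect_equal(cond$B9$missing_high, 22L)
})

test_that("column totals are 311/76 except the flagged transcription typos", {
  cond <- bq_default_conditionals()
  flagged <- names(Filter(function(cd) length(cd$flags) > 0, cond))
  expect_setequal(flagged, c("Q19", "Q21", "Q30", "Q35"))
  for (cd in cond[setdiff(names(cond), flagged)]) {
    expect_equal(sum(cd$counts_low) + cd$missing_low, 311, info = cd$item_id)
    expect_equal(sum(cd$counts_high) + cd$missing_high, 76, info = cd$item_id)
  }
})

test_that("generator is seed-deterministic and honours prevalence bounds", {
  cfg <- bq_generator_config(n_subjects = 200, seed = 31)
  a <- bq_generate_cohort(cfg)
  b <- bq_generate_cohort(cfg)
  expect_identical(a, b)
  none <- bq_generate_cohort(bq_generator_config(n_subjects = 100,
                                                 prevalence = 0, seed = 2))
  expect_true(all(attr(none, "latent") == "low"))
  expect_equal(nrow(bq_generate_cohort(bq_generator_config(n_subjects = 0))), 0)
  expect_error(bq_generator_config(prevalence = 1.2), "prevalence")
})

test_that("skip logic keeps follow-ups consistent with their parents", {
  coh <- bq_generate_cohort(bq_generator_config(n_subjects = 2000, seed = 4))
  expect_true(all(is.na(coh$B2[coh$B1 == "No"])))
  b9_no <- coh$B9[coh$B8 == "No"]
  expect_true(all(is.na(b9_no) | b9_no == "Never or almost never"))
  # BMI stays inside the published range and matches its group column
  expect_true(all(coh$bmi >= 18 & coh$bmi <= 46))
  obese <- coh$Q3 == "Obese >=30"
  expect_true(all(coh$bmi[obese] >= 30))
  expect_true(all(coh$bmi[!obese] < 30))
})

test_that("generated frequencies recover the configured conditionals", {
  coh <- bq_generate_cohort(bq_generator_config(n_subjects = 8000, seed = 17))
  latent <- attr(coh, "latent")
  cond <- bq_default_conditionals()
  for (id in c("B1", "B5", "B10", "Q2", "Q38")) {
    cd <- cond[[id]]
    for (cls in c("low", "high")) {
      expected <- if (cls == "low") cd$counts_low else cd$counts_high
      obs <- table(factor(coh[[id]][latent == cls], levels = cd$levels))
      keep <- expected > 0
      p <- suppressWarnings(
        chisq.test(as.numeric(obs[keep]), p = expected[keep] / sum(expected[keep]))$p.value)
      expect_gt(p, 0.001)
    }
  }
})

test_that("recomputed labels associate with the latent class", {
  coh <- bq_generate_cohort(bq_generator_config(n_subjects = 1000, seed = 23))
  tab <- table(attr(coh, "latent"), attr(coh, "label"))
  or <- (tab["high", "high"] * tab["low", "low"]) /
        (tab["high", "low"] * tab["low", "high"])
  expect_gt(or, 1)
})

test_that("recomputed prevalence is stable near the study rate across seeds", {
  prev <- vapply(1:5, function(s) {
    coh <- bq_generate_cohort(bq_generator_config(n_subjects = 800, seed = s))
    mean(attr(coh, "label") == "high")
  }, 0)
  expect_gt(mean(prev), 0.10)
  expect_lt(mean(prev), 0.30)
  expect_lt(sd(prev), 0.05)
})

test_that("extra missingness is applied at the requested rates", {
  coh <- bq_generate_cohort(bq_generator_config(n_subjects = 10000, seed = 3))
  same <- bq_apply_missingness(coh, c(B6 = 0), seed = 1)
  expect_identical(coh$B6, same$B6)
  all_gone <- bq_apply_missingness(coh, c(B6 = 1), seed = 1)
  expect_true(all(is.na(all_gone$B6)))
  some <- bq_apply_missingness(coh, c(B3 = 0.2), seed = 1)
  expect_lt(abs(mean(is.na(some$B3)) - 0.2), 0.02)
  expect_error(bq_apply_missingness(coh, c(B3 = 1.5)), "rates")
})
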