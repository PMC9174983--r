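test_that("category scoring follows the two-of-n symptom rules", {
  # hypertension/BMI category alone
  sc <- bq_score_categories(make_record(B10 = "Yes", bmi = 31))
  expect_equal(unlist(sc[1, 1:3]),
               c(cat1_positive = FALSE, cat2_positive = FALSE, cat3_positive = TRUE))
  # least symptomatic everywhere
  expect_equal(bq_score_categories(make_record())$positive_count, 0L)
  # two positive snoring answers make category 1 positive
  sc <- bq_score_categories(make_record(
    B1 = "Yes", B3 = "Every day", B2 = "Slightly louder than breathing"))
  expect_true(sc$cat1_positive)
  expect_false(sc$cat2_positive)
  # one positive answer is not enough
  expect_false(bq_score_categories(make_record(B1 = "Yes"))$cat1_positive)
  # BMI threshold is strictly > 30
  expect_false(bq_score_categories(make_record(bmi = 30))$cat3_positive)
  expect_true(bq_score_categories(make_record(bmi = 30.1))$cat3_positive)
})

test_that("missing answers never count positive and invalid levels reject", {
  rec <- make_record(B1 = NA, B2 = NA, B3 = NA, B4 = NA, B5 = NA)
  expect_false(bq_score_categories(rec)$cat1_positive)
  expect_error(bq_score_categories(make_record(B3 = "sometimes")), "invalid")
})

test_that("risk label is high exactly for >= 2 positive categories", {
  # drive each category independently and enumerate all 8 patterns
  drivers <- list(
    cat1 = list(B1 = "Yes", B4 = "Yes"),
    cat2 = list(B6 = "Every day", B7 = "Every day"),
    cat3 = list(B10 = "Yes")
  )
  for (p1 in c(FALSE, TRUE)) for (p2 in c(FALSE, TRUE)) for (p3 in c(FALSE, TRUE)) {
    args <- c(if (p1) drivers$cat1, if (p2) drivers$cat2, if (p3) drivers$cat3)
    rec <- do.call(make_record, as.list(args))
    sc <- bq_score_categories(rec)
    expect_equal(unlist(sc[1, 1:3]), c(cat1_positive = p1, cat2_positive = p2,
                                       cat3_positive = p3))
    expect_equal(as.character(bq_classify_risk(rec)),
                 if (p1 + p2 + p3 >= 2) "high" else "low")
  }
})

test_that("scoring is deterministic", {
  coh <- random_cohort(50, seed = 3)
  expect_identical(bq_classify_risk(coh), bq_classify_risk(coh))
})

test_that("escalating a single answer never flips high to low", {
  dict <- bq_item_dictionary(FALSE)
  coh <- random_cohort(500, seed = 7)
  labels <- bq_classify_risk(coh)
  set.seed(11)
  items <- c(bq_item_ids(dict, "bq"), "bmi")
  for (i in seq_len(nrow(coh))) {
    id <- sample(items, 1)
    esc <- coh[i, , drop = FALSE]
    if (id == "bmi") {
      esc$bmi <- esc$bmi + runif(1, 0, 20)
    } else {
      lv <- dict[[id]]$levels
      pos <- match(esc[[id]], lv)
      if (pos == length(lv)) next
      esc[[id]] <- lv[pos + sample.int(length(lv) - pos, 1)]
    }
    if (labels[i] == "high") {
      expect_equal(as.character(bq_classify_risk(esc)), "high",
                   info = paste("row", i, "item", id))
    }
  }
})

test_that("ordinal encoding follows dictionary order and DK policy", {
  coh <- rbind(make_record(), make_record(B1 = "Do not know"),
               make_record(B1 = "Yes", B3 = "Every day"))
  mid <- bq_encode(coh, policy = bq_encoding_policy("as_middle"))
  expect_equal(mid$x[, "B1"], c(0, 1, 2))
  expect_equal(unname(mid$x[3, "B3"]), 4)
  mis <- bq_encode(coh, policy = bq_encoding_policy("as_missing"))
  expect_equal(mis$x[, "B1"], c(0, NA, 2))
  # skip-logic missing answers become the missing marker; rows are kept
  expect_true(all(is.na(mis$x[, "B2"])))
  expect_equal(nrow(mis$x), 3)
  expect_equal(mis$x[, "BMI"], c(22, 22, 22))
})

test_that("labels in an encoded dataset equal row-wise risk classification", {
  coh <- random_cohort(120, seed = 5)
  enc <- bq_encode(coh)
  expect_identical(enc$labels, bq_classify_risk(coh))
})

test_that("encoding round-trips non-missing answers", {
  dict <- bq_item_dictionary(FALSE)
  coh <- random_cohort(40, seed = 9)
  enc <- bq_encode(coh, policy = bq_encoding_policy("as_middle"))
  for (id in bq_item_ids(dict, "bq")) {
    decoded <- dict[[id]]$levels[enc$x[, id] + 1]
    expect_equal(decoded, coh[[id]], info = id)
  }
})

test_that("encoding rejects empty cohorts and unknown levels", {
  expect_error(bq_encode(make_record()[0, ]), "empty")
  expect_error(bq_encode(make_record(B1 = "nope")), "invalid|unknown")
})
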