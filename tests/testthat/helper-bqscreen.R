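# shared fixtures built in code

# a fully least-symptomatic record; override individual answers as needed
make_record <- function(...) {
  rec <- data.frame(
    B1 = "No", B2 = NA_character_, B3 = "Never or almost never",
    B4 = "No", B5 = "Never or almost never", B6 = "Never or almost never",
    B7 = "Never or almost never", B8 = "No", B9 = "Never or almost never",
    B10 = "No", bmi = 22,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# random valid cohort over the BQ items (uniform over levels, no missing)
random_cohort <- function(n, dict = bq_item_dictionary(FALSE), seed = 1) {
  set.seed(seed)
  cols <- lapply(bq_item_ids(dict, "bq"), function(id) {
    sample(dict[[id]]$levels, n, replace = TRUE)
  })
  names(cols) <- bq_item_ids(dict, "bq")
  coh <- as.data.frame(cols, stringsAsFactors = FALSE)
  coh$bmi <- round(runif(n, 18, 46), 1)
  coh
}

# stub scorer reading one column when present, constant otherwise
stub_on <- function(col) {
  bq_classifier_stub(function(x) {
    if (col %in% colnames(x)) x[, col] else rep(0.5, nrow(x))
  })
}

# small programmatic dataset with a label-defining binary feature + noise
planted_dataset <- function(n = 200, n_noise = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("low", "high"), c(round(0.8 * n), n - round(0.8 * n)))
  x <- cbind(signal = as.numeric(y == "high"),
             matrix(rnorm(n * n_noise), n, n_noise,
                    dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  bq_encoded(x, y)
}
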