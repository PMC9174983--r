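# small shared helpers

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables round 0.5 up, so
#' percentage reproduction needs explicit half-up rounding.
#'
#' @param x numeric vector
#' @param digits integer number of decimal digits
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive `n` reproducible child seeds (< 2^31) from one integer seed without
# disturbing the caller's RNG stream ordering guarantees beyond set.seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

# Largest-remainder allocation of `total` among groups proportional to sizes.
allocate_proportional <- function(sizes, total) {
  quota <- sizes * total / sum(sizes)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Stratified fold assignment: within each class, deal shuffled indices
# round-robin so every fold keeps both classes where possible.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
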