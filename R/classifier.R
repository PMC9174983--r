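# Trainable binary scorer contract used by the selection protocol. A
# classifier is a list with `fit(x, y, seed)` returning a fitted model and
# `score(model, x)` returning class-probability-like values (higher = more
# likely high risk). It must accept NA entries in `x` natively.

#' Gradient-boosted-tree classifier (xgboost backend)
#'
#' The default protocol scorer: binary logistic gradient boosting with
#' native sparsity-aware missing-value handling, so no imputation is ever
#' applied to skipped or unanswered items. Row subsampling (default 0.8)
#' makes refitting under a new seed genuinely stochastic, which is what the
#' protocol's repeat-and-average steps exercise; single-threaded histogram
#' trees make a given seed fully deterministic.
#'
#' @param nrounds boosting rounds (default 100)
#' @param max_depth tree depth (default 3)
#' @param eta learning rate (default 0.1)
#' @param subsample row subsampling fraction per round (default 0.8)
#' @return object of class `bq_classifier`
#' @export
bq_classifier_xgb <- function(nrounds = 100, max_depth = 3, eta = 0.1,
                              subsample = 0.8) {
  force(nrounds); force(max_depth); force(eta); force(subsample)
  structure(list(
    name = sprintf("xgboost(nrounds=%d, depth=%d, eta=%g, subsample=%g)",
                   nrounds, max_depth, eta, subsample),
    fit = function(x, y, seed = 1L) {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = as.numeric(y),
                                     nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, subsample = subsample, nthread = 1,
                      tree_method = "hist", seed = as.integer(seed)),
        data = dtrain, nrounds = nrounds, verbose = 0)
    },
    score = function(model, x) {
      stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))
    }
  ), class = "bq_classifier")
}

#' Deterministic stub classifier
#'
#' A non-learning scorer for tests and oracle equivalences: `score_fun`
#' maps a feature matrix to scores, and fitting is a no-op. Seed-invariant
#' by construction.
#'
#' @param score_fun function(matrix) -> numeric scores
#' @return object of class `bq_classifier`
#' @export
bq_classifier_stub <- function(score_fun) {
  force(score_fun)
  structure(list(
    name = "stub",
    fit = function(x, y, seed = 1L) list(score_fun = score_fun),
    score = function(model, x) model$score_fun(as.matrix(x))
  ), class = "bq_classifier")
}

#' @export
print.bq_classifier <- function(x, ...) {
  cat("<bq_classifier> ", x$name, "\n", sep = "")
  invisible(x)
}
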