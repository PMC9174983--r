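# The robustness-voted backward sequential feature-selection protocol.
#
# The dataset is split once into a selection part P1 (70%) and a quality
# assessment part P2 (30%). At each elimination step, instead of trusting a
# single backward-selection pass, the one-feature elimination is repeated R
# times (default 100) on reshuffled P1 data with a reseeded classifier; each
# repetition downvotes the feature whose removal costs least, and the
# feature with the most downvotes is eliminated. Every surviving subset is
# scored on P2 by repeated refitting (default 50 reps), giving an AUROC vs
# cardinality curve with uncertainties. The whole procedure is repeated over
# many P1/P2 splits to measure how stable the small "best" subsets are.

#' Protocol configuration
#'
#' @param train_frac fraction of the data in the selection part P1
#'   (default 0.70; P2 gets the rest)
#' @param inner_reps R, shuffled downvoting repetitions per elimination step
#'   (default 100)
#' @param eval_reps refit repetitions when scoring a subset on P2 or in CV
#'   (default 50)
#' @param outer_runs protocol repetitions with fresh P1/P2 splits
#'   (default 60)
#' @param cv_folds folds for [bq_cv_auroc()] (default 5)
#' @param subset_size k, the cardinality of the "best" subsets aggregated
#'   across runs (default 3)
#' @param seed master seed; every random draw in the protocol derives from it
#' @param classifier a `bq_classifier` (default [bq_classifier_xgb()])
#' @return object of class `bq_protocol_config`
#' @export
bq_protocol_config <- function(train_frac = 0.7, inner_reps = 100,
                               eval_reps = 50, outer_runs = 60,
                               cv_folds = 5, subset_size = 3, seed = 1L,
                               classifier = bq_classifier_xgb()) {
  stopifnot(inner_reps >= 1, eval_reps >= 1, outer_runs >= 1,
            cv_folds >= 2, subset_size >= 1,
            inherits(classifier, "bq_classifier"))
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly between 0 and 1 (P1 and P2 both non-empty)")
  }
  structure(
    list(train_frac = train_frac, inner_reps = as.integer(inner_reps),
         eval_reps = as.integer(eval_reps), outer_runs = as.integer(outer_runs),
         cv_folds = as.integer(cv_folds), subset_size = as.integer(subset_size),
         seed = as.integer(seed), classifier = classifier),
    class = "bq_protocol_config"
  )
}

# Stratified draw of floor(frac * n) indices using the current RNG stream.
# Per-class allocation by largest remainder, clamped so both sides keep at
# least one member of every class (when the class has >= 2 members).
stratified_take <- function(labels, frac) {
  n <- length(labels)
  n_take <- floor(frac * n)
  classes <- levels(factor(labels))
  sizes <- vapply(classes, function(cl) sum(labels == cl), 0L)
  alloc <- allocate_proportional(sizes, n_take)
  alloc <- pmin(pmax(alloc, ifelse(sizes >= 2, 1L, 0L)), pmax(sizes - 1L, 0L))
  unlist(lapply(seq_along(classes), function(i) {
    idx <- which(labels == classes[i])
    sample(idx, alloc[i])
  }), use.names = FALSE)
}

#' Split an encoded dataset into selection and assessment parts
#'
#' Stratified-by-label random split with `|P1| = floor(train_frac * N)`.
#' If either part ends up missing a class (possible only for degenerate
#' inputs), the split is redrawn with the next seed and a warning is given.
#'
#' @param encoded a [bq_encode()] result
#' @param train_frac P1 fraction
#' @param seed integer seed
#' @return list with encoded parts `P1` and `P2` and the `seed` used
#' @export
bq_split_dataset <- function(encoded, train_frac = 0.7, seed = 1L) {
  stopifnot(inherits(encoded, "bq_encoded"))
  if (nrow(encoded$x) < 10) stop("dataset too small to split (need >= 10 rows)")
  if (nlevels(droplevels(encoded$labels)) < 2) stop("both classes must be present")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  for (s in seed + 0:9) {
    set.seed(s)
    take <- stratified_take(encoded$labels, train_frac)
    p1 <- encoded_subset(encoded, take)
    p2 <- encoded_subset(encoded, setdiff(seq_along(encoded$labels), take))
    ok <- nlevels(droplevels(p1$labels)) == 2 && nlevels(droplevels(p2$labels)) == 2
    if (ok) {
      if (s != seed) warning("split redrawn with seed ", s, " to keep both classes")
      return(list(P1 = p1, P2 = p2, seed = s))
    }
  }
  stop("could not produce a split containing both classes in both parts")
}

# AUROC of classifier scores against low/high labels.
score_auroc <- function(scores, labels) {
  bq_rank_auroc(scores[labels == "low"], scores[labels == "high"])
}

#' One robustness-voted elimination step
#'
#' Repeats the single backward-elimination decision `inner_reps` times. Each
#' repetition redraws a stratified internal split of P1 (the shuffle that
#' drives repetition-to-repetition variability) and reseeds the classifier;
#' every candidate feature is scored by the internal validation AUROC of the
#' model fitted *without* it, and the feature whose absence hurts least is
#' downvoted. The step removes the feature with the most downvotes; tallies
#' tie-break toward earlier questionnaire item order.
#'
#' @param P1 encoded selection dataset
#' @param features candidate feature ids (>= 2)
#' @param config a [bq_protocol_config()]
#' @param seed step seed (defaults to the config seed)
#' @return list: `features`, `tally` (downvotes per feature, summing to
#'   `inner_reps`), `removed`
#' @export
bq_downvote_round <- function(P1, features, config = bq_protocol_config(),
                              seed = config$seed) {
  stopifnot(inherits(P1, "bq_encoded"))
  if (length(features) < 2) stop("need at least 2 candidate features")
  clf <- config$classifier
  tally <- stats::setNames(integer(length(features)), features)
  rep_seeds <- derive_seeds(seed, config$inner_reps)
  for (r in seq_len(config$inner_reps)) {
    set.seed(rep_seeds[r])
    tr <- stratified_take(P1$labels, config$train_frac)
    va <- setdiff(seq_along(P1$labels), tr)
    auroc_without <- vapply(features, function(f) {
      keep <- setdiff(features, f)
      model <- clf$fit(P1$x[tr, keep, drop = FALSE],
                       P1$labels[tr] == "high", seed = rep_seeds[r])
      score_auroc(clf$score(model, P1$x[va, keep, drop = FALSE]), P1$labels[va])
    }, 0)
    tally[features[which.max(auroc_without)]] <-
      tally[features[which.max(auroc_without)]] + 1L
  }
  list(features = features, tally = tally,
       removed = features[which.max(tally)])
}

#' Score a feature subset on the assessment part
#'
#' `eval_reps` repetitions of reseed + refit on P1 restricted to the subset,
#' scoring P2; returns the mean AUROC and its standard deviation over
#' repetitions.
#'
#' @param P1,P2 encoded selection / assessment datasets
#' @param subset feature ids (non-empty)
#' @param config a [bq_protocol_config()]
#' @param seed evaluation seed
#' @return list with `mean`, `sd` and the per-repetition `aurocs`
#' @export
bq_evaluate_subset <- function(P1, P2, subset, config = bq_protocol_config(),
                               seed = config$seed) {
  stopifnot(length(subset) >= 1)
  if (nlevels(droplevels(P2$labels)) < 2) stop("P2 must contain both classes")
  clf <- config$classifier
  rep_seeds <- derive_seeds(seed, config$eval_reps)
  aurocs <- vapply(rep_seeds, function(s) {
    model <- clf$fit(P1$x[, subset, drop = FALSE], P1$labels == "high", seed = s)
    score_auroc(clf$score(model, P2$x[, subset, drop = FALSE]), P2$labels)
  }, 0)
  list(mean = mean(aurocs),
       sd = if (length(aurocs) > 1) stats::sd(aurocs) else 0,
       aurocs = aurocs)
}

#' Run the full backward selection protocol
#'
#' Splits the data into P1/P2, then eliminates one feature per step (each
#' step decided by [bq_downvote_round()]) from the full feature set down to
#' a single survivor, scoring every surviving subset on P2. Fully
#' deterministic given `(dataset, config$seed)`.
#'
#' @param encoded a [bq_encode()] result
#' @param config a [bq_protocol_config()]
#' @param features starting feature set (default: all encoded features)
#' @return object of class `bq_selection_trace`: `curve` (data frame
#'   cardinality / mean_auroc / sd_auroc / features), `steps` (per-step
#'   downvote records), `removal_order` (all features, least predictive
#'   first), `subsets` (surviving set at each cardinality), `split_seed`
#' @export
bq_run_protocol <- function(encoded, config = bq_protocol_config(),
                            features = encoded$features) {
  n <- length(features)
  if (n < 2) stop("need at least 2 features")
  seeds <- derive_seeds(config$seed, 2 * n)
  split <- bq_split_dataset(encoded, config$train_frac, seeds[1])

  current <- features
  subsets <- stats::setNames(vector("list", n), as.character(n:1))
  curve <- data.frame(cardinality = n:1, mean_auroc = NA_real_,
                      sd_auroc = NA_real_, features = NA_character_)
  record_eval <- function(card, ev, feats) {
    i <- which(curve$cardinality == card)
    curve$mean_auroc[i] <<- ev$mean
    curve$sd_auroc[i] <<- ev$sd
    curve$features[i] <<- paste(feats, collapse = ",")
    subsets[[as.character(card)]] <<- feats
  }
  record_eval(n, bq_evaluate_subset(split$P1, split$P2, current, config, seeds[2]),
              current)

  steps <- vector("list", n - 1)
  removal_order <- character(0)
  for (m in 0:(n - 2)) {
    step <- bq_downvote_round(split$P1, current, config, seeds[2 * m + 3])
    current <- setdiff(current, step$removed)
    removal_order <- c(removal_order, step$removed)
    ev <- bq_evaluate_subset(split$P1, split$P2, current, config, seeds[2 * m + 4])
    steps[[m + 1]] <- c(step, list(step = m, mean_auroc = ev$mean, sd_auroc = ev$sd))
    record_eval(length(current), ev, current)
  }
  structure(
    list(curve = curve, steps = steps,
         removal_order = c(removal_order, current),
         subsets = subsets, split_seed = split$seed, config = config),
    class = "bq_selection_trace"
  )
}

#' @export
print.bq_selection_trace <- function(x, ...) {
  cat("<bq_selection_trace> removal order (least predictive first):\n  ",
      paste(x$removal_order, collapse = " < "), "\n", sep = "")
  print(x$curve[, c("cardinality", "mean_auroc", "sd_auroc")], row.names = FALSE)
  invisible(x)
}

#' Surviving subset at a given cardinality
#'
#' @param trace a [bq_run_protocol()] result
#' @param k cardinality
#' @return character vector of feature ids
#' @export
bq_best_subset <- function(trace, k = trace$config$subset_size) {
  out <- trace$subsets[[as.character(k)]]
  if (is.null(out)) stop("no subset of cardinality ", k, " in this trace")
  out
}

#' Aggregate the protocol over many dataset splits
#'
#' Runs [bq_run_protocol()] `outer_runs` times with different split seeds,
#' collects the size-k surviving subset of each run, and reports per-feature
#' selection frequencies.
#'
#' @param encoded a [bq_encode()] result
#' @param config a [bq_protocol_config()]
#' @param features starting feature set
#' @return object of class `bq_run_aggregate`: `best_subsets` (list),
#'   `frequency` (named, descending), `k`, `n_runs`
#' @export
bq_aggregate_runs <- function(encoded, config = bq_protocol_config(),
                              features = encoded$features) {
  run_seeds <- derive_seeds(config$seed, config$outer_runs)
  subsets <- lapply(run_seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    bq_best_subset(bq_run_protocol(encoded, cfg, features), config$subset_size)
  })
  freq <- vapply(features, function(f) {
    mean(vapply(subsets, function(s) f %in% s, TRUE))
  }, 0)
  structure(
    list(best_subsets = subsets, frequency = sort(freq, decreasing = TRUE),
         k = config$subset_size, n_runs = config$outer_runs),
    class = "bq_run_aggregate"
  )
}

#' @export
print.bq_run_aggregate <- function(x, ...) {
  cat("<bq_run_aggregate> size-", x$k, " subsets over ", x$n_runs, " runs\n",
      "selection frequency:\n", sep = "")
  print(round(x$frequency, 3))
  invisible(x)
}

#' Normalized co-occurrence matrix of best subsets
#'
#' Counts how often each unordered pair of features appears together in the
#' best subsets and normalizes by the total number of pair occurrences, so
#' the upper triangle sums to 1.
#'
#' @param best_subsets list of character vectors (e.g. from
#'   [bq_aggregate_runs()])
#' @param features optional feature ordering for the matrix (default: order
#'   of first appearance)
#' @return symmetric numeric matrix with attribute `"normalizer"` (the
#'   total pair count)
#' @export
bq_cooccurrence <- function(best_subsets, features = NULL) {
  stopifnot(length(best_subsets) >= 1)
  feats <- features %||% unique(unlist(best_subsets))
  m <- matrix(0, length(feats), length(feats), dimnames = list(feats, feats))
  total <- 0
  for (s in best_subsets) {
    s <- intersect(feats, s)
    if (length(s) < 2) next
    for (pair in utils::combn(s, 2, simplify = FALSE)) {
      m[pair[1], pair[2]] <- m[pair[1], pair[2]] + 1
      m[pair[2], pair[1]] <- m[pair[2], pair[1]] + 1
      total <- total + 1
    }
  }
  if (total == 0) {
    warning("all subsets are singletons; empty co-occurrence matrix")
    return(structure(m, normalizer = 0))
  }
  structure(m / total, normalizer = total)
}

#' Repeated stratified k-fold cross-validated AUROC
#'
#' Evaluates a candidate reduced questionnaire on the whole dataset:
#' `eval_reps` repetitions of stratified `cv_folds`-fold CV with reshuffled
#' fold assignments; within a repetition the out-of-fold scores are pooled
#' into a single AUROC. Returns mean and SD over repetitions.
#'
#' @param encoded a [bq_encode()] result
#' @param subset feature ids to evaluate
#' @param config a [bq_protocol_config()]
#' @return list with `mean`, `sd`, `aurocs`
#' @export
bq_cv_auroc <- function(encoded, subset, config = bq_protocol_config()) {
  stopifnot(length(subset) >= 1)
  if (nlevels(droplevels(encoded$labels)) < 2) stop("both classes must be present")
  clf <- config$classifier
  rep_seeds <- derive_seeds(config$seed, config$eval_reps)
  x <- encoded$x[, subset, drop = FALSE]
  y <- encoded$labels
  aurocs <- vapply(rep_seeds, function(s) {
    set.seed(s)
    folds <- stratified_folds(y, config$cv_folds)
    scores <- numeric(length(y))
    for (k in seq_len(config$cv_folds)) {
      tr <- folds != k
      model <- clf$fit(x[tr, , drop = FALSE], y[tr] == "high", seed = s)
      scores[!tr] <- clf$score(model, x[!tr, , drop = FALSE])
    }
    score_auroc(scores, y)
  }, 0)
  list(mean = mean(aurocs),
       sd = if (length(aurocs) > 1) stats::sd(aurocs) else 0,
       aurocs = aurocs)
}
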