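# Descriptive and inferential comparisons between the low- and high-risk
# groups: per-item contingency tables, class percentages, chi-square /
# Fisher exact tests for categorical association, and rank tests
# (Mann-Whitney / Kruskal-Wallis) for ordinal shift.

#' Per-item contingency table by risk group
#'
#' Cross-tabulates one item's response levels against the recomputed
#' high/low BQ label. Missing answers are tracked separately and excluded
#' from the level counts.
#'
#' @param cohort subject-level data frame
#' @param item_id item to tabulate
#' @param labels optional precomputed label factor; defaults to
#'   [bq_classify_risk()] on the cohort
#' @param dict item dictionary
#' @return object of class `bq_xtab`
#' @export
bq_crosstab <- function(cohort, item_id, labels = NULL,
                        dict = bq_item_dictionary()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) stop("empty dataset")
  it <- dict[[item_id]]
  if (is.null(it) || it$type != "categorical") stop("unknown categorical item: ", item_id)
  if (!item_id %in% names(cohort)) stop("item not present in cohort: ", item_id)
  labels <- labels %||% bq_classify_risk(cohort, dict)
  vals <- factor(as.character(cohort[[item_id]]), levels = it$levels)
  counts <- table(vals, labels)[, c("low", "high"), drop = FALSE]
  bq_xtab(item_id, it$levels,
          counts_low = counts[, "low"], counts_high = counts[, "high"],
          missing_low = sum(is.na(vals) & labels == "low"),
          missing_high = sum(is.na(vals) & labels == "high"))
}

#' Construct a contingency table from counts
#'
#' Used both by [bq_crosstab()] and to enter published grouped counts
#' directly.
#'
#' @param item_id item identifier (free text allowed)
#' @param levels ordered level labels
#' @param counts_low,counts_high nonnegative level counts per class
#' @param missing_low,missing_high missing counts per class
#' @return object of class `bq_xtab`
#' @export
bq_xtab <- function(item_id, levels, counts_low, counts_high,
                    missing_low = 0L, missing_high = 0L) {
  stopifnot(length(levels) == length(counts_low),
            length(counts_low) == length(counts_high),
            all(counts_low >= 0), all(counts_high >= 0))
  counts <- cbind(low = as.integer(counts_low), high = as.integer(counts_high))
  rownames(counts) <- levels
  n <- colSums(counts) + c(missing_low, missing_high)
  if (any(n == 0)) stop("a class has zero total")
  structure(
    list(item_id = item_id, levels = levels, counts = counts,
         missing = c(low = as.integer(missing_low), high = as.integer(missing_high)),
         n = n),
    class = "bq_xtab"
  )
}

#' Contingency table from a class-conditional table
#'
#' @param cond a [bq_conditional()]
#' @return object of class `bq_xtab`
#' @export
bq_xtab_from_conditional <- function(cond) {
  bq_xtab(cond$item_id, cond$levels, cond$counts_low, cond$counts_high,
          cond$missing_low, cond$missing_high)
}

#' @export
print.bq_xtab <- function(x, ...) {
  cat("<bq_xtab> ", x$item_id, " (n low = ", x$n["low"], ", high = ",
      x$n["high"], ")\n", sep = "")
  m <- x$counts
  if (sum(x$missing) > 0) m <- rbind(m, `(missing)` = x$missing)
  print(m)
  invisible(x)
}

#' Per-class level percentages
#'
#' Percentages are taken of the full class total (missing shown as its own
#' row, as in published questionnaire tables). Both the raw percentage and
#' the display value (half-up integer rounding) are returned.
#'
#' @param xtab a [bq_xtab()]
#' @return data frame with one row per level (plus a `(missing)` row when
#'   applicable): counts, raw and rounded percentages per class
#' @examples
#' ht <- bq_xtab("B10", c("No", "Yes", "Do not know"),
#'               c(284, 16, 11), c(33, 39, 4))
#' bq_group_percentages(ht)
#' @export
bq_group_percentages <- function(xtab) {
  stopifnot(inherits(xtab, "bq_xtab"))
  counts <- xtab$counts
  if (sum(xtab$missing) > 0) counts <- rbind(counts, `(missing)` = xtab$missing)
  pct_low <- 100 * counts[, "low"] / xtab$n["low"]
  pct_high <- 100 * counts[, "high"] / xtab$n["high"]
  data.frame(
    level = rownames(counts),
    count_low = counts[, "low"], pct_low_raw = pct_low,
    pct_low = round_half_up(pct_low),
    count_high = counts[, "high"], pct_high_raw = pct_high,
    pct_high = round_half_up(pct_high),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.test_result <- function(name, statistic, p, dof = NA_integer_) {
  structure(list(test_name = name, statistic = unname(statistic),
                 p_value = unname(p), dof = unname(dof)),
            class = "bq_test_result")
}

#' @export
print.bq_test_result <- function(x, ...) {
  cat("<bq_test_result> ", x$test_name,
      ": statistic = ", signif(x$statistic, 4),
      if (!is.na(x$dof)) paste0(", dof = ", x$dof),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, on the level counts
#' (missing rows excluded); levels with zero overall count are dropped.
#'
#' @param xtab a [bq_xtab()] (or plain counts matrix)
#' @return a `bq_test_result`
#' @export
bq_chisq_test <- function(xtab) {
  m <- if (inherits(xtab, "bq_xtab")) xtab$counts else as.matrix(xtab)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) stop("degenerate table: need >= 2 nonzero rows and columns")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  .test_result("chi_square", res$statistic, res$p.value, as.integer(res$parameter))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided conditional exact test. Tables with more than two levels can be
#' collapsed first by naming the level(s) forming the first row.
#'
#' @param xtab a [bq_xtab()] or 2x2 counts matrix
#' @param collapse optional character vector of levels forming the first row
#'   of the collapsed 2x2 table (the remaining levels form the second)
#' @return a `bq_test_result`
#' @export
bq_fisher_exact <- function(xtab, collapse = NULL) {
  m <- if (inherits(xtab, "bq_xtab")) xtab$counts else as.matrix(xtab)
  if (!is.null(collapse)) {
    top <- colSums(m[rownames(m) %in% collapse, , drop = FALSE])
    bot <- colSums(m[!rownames(m) %in% collapse, , drop = FALSE])
    m <- rbind(top, bot)
  }
  if (!all(dim(m) == c(2, 2))) stop("Fisher exact test requires a 2x2 table")
  res <- stats::fisher.test(m)
  .test_result("fisher_exact", res$estimate, res$p.value)
}

#' Rank test for ordinal shift between risk groups
#'
#' Encodes the item ordinally and runs a two-sample Mann-Whitney U test
#' (normal approximation with tie correction) of high vs low; with a
#' `groups` factor of more than two levels a Kruskal-Wallis test is run
#' instead. The reported Mann-Whitney statistic is the number of
#' (high > low) pairs plus half the ties, so `statistic / (n1*n2)` equals
#' the rank AUROC of the same data.
#'
#' @param cohort subject-level data frame
#' @param item_id ordinal item to test
#' @param groups optional alternative grouping factor (default: the
#'   recomputed BQ label)
#' @param policy encoding policy for the item's levels
#' @param dict item dictionary
#' @return a `bq_test_result`
#' @export
bq_rank_test <- function(cohort, item_id, groups = NULL,
                         policy = bq_encoding_policy(),
                         dict = bq_item_dictionary()) {
  it <- dict[[item_id]]
  if (is.null(it)) stop("unknown item: ", item_id)
  v <- if (it$type == "numeric") as.numeric(cohort[[tolower(item_id)]] %||% cohort[[item_id]])
       else encode_levels(as.character(cohort[[item_id]]), it, policy)
  groups <- groups %||% bq_classify_risk(cohort, dict)
  keep <- !is.na(v) & !is.na(groups)
  v <- v[keep]; groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) > 2) {
    res <- stats::kruskal.test(v, groups)
    return(.test_result("kruskal_wallis", res$statistic, res$p.value,
                        as.integer(res$parameter)))
  }
  if (nlevels(groups) < 2) stop("one class is empty after missing removal")
  x_high <- v[groups == levels(groups)[2]]
  x_low <- v[groups == levels(groups)[1]]
  u <- bq_rank_auroc(x_low, x_high) * length(x_low) * length(x_high)
  p <- suppressWarnings(
    stats::wilcox.test(x_high, x_low, exact = FALSE, correct = FALSE)$p.value)
  .test_result("mann_whitney", u, p)
}

#' Summary comparison table across items
#'
#' Builds the published-style per-item summary: level counts and percentages
#' per risk group, an association test, and significance stars (`*`, `**`,
#' `***` at 0.05 / 0.01 / 0.001). Test routing: Pearson chi-square by
#' default; Fisher exact when the table is 2x2 and any expected cell is
#' below 5; the Mann-Whitney p-value is reported alongside for ordinal
#' (3+ level) items.
#'
#' @param cohort subject-level data frame
#' @param items item ids to summarize
#' @param policy encoding policy for rank tests
#' @param dict item dictionary
#' @return data frame, one row per item level, with the item-level test
#'   repeated on its first row
#' @export
bq_summary_table <- function(cohort, items = bq_item_ids(dict, "bq"),
                             policy = bq_encoding_policy(),
                             dict = bq_item_dictionary()) {
  labels <- bq_classify_risk(cohort, dict)
  rows <- lapply(items, function(id) {
    xt <- bq_crosstab(cohort, id, labels = labels, dict = dict)
    pct <- bq_group_percentages(xt)
    m <- xt$counts[rowSums(xt$counts) > 0, , drop = FALSE]
    test <- tryCatch({
      expected <- outer(rowSums(m), colSums(m)) / sum(m)
      if (all(dim(m) == c(2, 2)) && any(expected < 5)) bq_fisher_exact(m)
      else bq_chisq_test(m)
    }, error = function(e) .test_result("none", NA_real_, NA_real_))
    rank_p <- if (length(dict[[id]]$levels) > 2) {
      tryCatch(bq_rank_test(cohort, id, policy = policy, dict = dict)$p_value,
               error = function(e) NA_real_)
    } else NA_real_
    first <- c(TRUE, rep(FALSE, nrow(pct) - 1))
    data.frame(
      item_id = id, text = dict[[id]]$text, pct,
      test = ifelse(first, test$test_name, ""),
      p_value = ifelse(first, test$p_value, NA),
      stars = ifelse(first & !is.na(test$p_value),
                     significance_stars(test$p_value), ""),
      rank_p = ifelse(first, rank_p, NA),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
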