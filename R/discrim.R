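# Single-variable discrimination scoring. Two complementary indices per
# item: the Fisher score F = (mean_low - mean_high)^2 / (var_low + var_high)
# with population (divide-by-n) variances, and the rank-based AUROC,
#   AUROC = (#\{high > low pairs\} + 0.5 * #ties) / (n_low * n_high),
# the probability that a randomly drawn high-class value exceeds a randomly
# drawn low-class value, ties half-credited. Both are computable either from
# individual values or in closed form from grouped level x class counts.

#' Fisher score between two classes
#'
#' `F = (mean(low) - mean(high))^2 / (var(low) + var(high))`, variances
#' maximum-likelihood (divide by n). A larger F means better univariate
#' separation. If both variances are zero the score is 0 for equal means and
#' `Inf` for distinct means.
#'
#' @param values_low,values_high numeric vectors of the variable in each
#'   class (non-empty; `NA` not allowed — drop missing upstream)
#' @return nonnegative scalar (possibly `Inf`)
#' @examples
#' bq_fisher_score(c(0, 1), c(2, 3))  # (0.5-2.5)^2 / (0.25+0.25) = 8
#' @export
bq_fisher_score <- function(values_low, values_high) {
  stopifnot(length(values_low) > 0, length(values_high) > 0,
            !anyNA(values_low), !anyNA(values_high))
  pvar <- function(x) mean((x - mean(x))^2)
  num <- (mean(values_low) - mean(values_high))^2
  den <- pvar(values_low) + pvar(values_high)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Rank-based AUROC of a single variable
#'
#' Computed from the Mann-Whitney identity
#' `AUROC = U / (n_low * n_high)` with ties half-credited. Orientation is
#' fixed by the coding direction — more symptomatic codes are expected to be
#' larger in the high class — and is never auto-flipped, so values below 0.5
#' indicate reversed coding.
#'
#' @inheritParams bq_fisher_score
#' @return scalar in `[0, 1]`
#' @examples
#' bq_rank_auroc(c(0, 0, 1), c(1, 2))  # 5.5 / 6
#' @export
bq_rank_auroc <- function(values_low, values_high) {
  stopifnot(length(values_low) > 0, length(values_high) > 0,
            !anyNA(values_low), !anyNA(values_high))
  n1 <- length(values_low); n2 <- length(values_high)
  r <- rank(c(values_low, values_high))
  u <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  u / (n1 * n2)
}

#' Discrimination scores from grouped counts, in closed form
#'
#' Evaluates both indices directly from a level x class contingency table,
#' without expanding to individuals: level codes come from the dictionary
#' order under the encoding policy ("Do not know" dropped or kept per
#' policy), and the pair counts / moments are computed from the weighted
#' level masses. The result is identical to expanding the counts into
#' individual records and calling [bq_fisher_score()] / [bq_rank_auroc()].
#'
#' @param xtab a [bq_xtab()]
#' @param policy a [bq_encoding_policy()]
#' @param dict item dictionary; used for level codes when the table's item
#'   is a dictionary item, otherwise codes fall back to the table's own
#'   level order
#' @return object of class `bq_discrim`: `item_id`, `auroc`, `fisher_f`,
#'   `n_low`, `n_high`, `policy`
#' @examples
#' ht <- bq_xtab("B10", c("No", "Do not know", "Yes"),
#'               c(284, 11, 16), c(33, 4, 39))
#' bq_grouped_scores(ht)  # AUROC 0.74, F 0.80
#' @export
bq_grouped_scores <- function(xtab, policy = bq_encoding_policy(),
                              dict = bq_item_dictionary()) {
  stopifnot(inherits(xtab, "bq_xtab"))
  it <- dict[[xtab$item_id]]
  codes <- if (!is.null(it) && it$type == "categorical") {
    encode_levels(xtab$levels, it, policy)
  } else {
    cd <- seq_along(xtab$levels) - 1
    if (policy$dontknow == "as_missing") cd[xtab$levels == "Do not know"] <- NA
    cd
  }
  keep <- !is.na(codes)
  codes <- codes[keep]
  wl <- as.numeric(xtab$counts[keep, "low"])
  wh <- as.numeric(xtab$counts[keep, "high"])
  o <- order(codes)
  codes <- codes[o]; wl <- wl[o]; wh <- wh[o]
  nl <- sum(wl); nh <- sum(wh)
  if (nl == 0 || nh == 0) stop("a class is empty after missing removal")

  # pair counting over sorted distinct codes
  gt <- sum(wh * cumsum(c(0, wl[-length(wl)])))   # high strictly above low
  ties <- sum(wh * wl)
  auroc <- (gt + 0.5 * ties) / (nl * nh)

  ml <- sum(wl * codes) / nl
  mh <- sum(wh * codes) / nh
  vl <- sum(wl * (codes - ml)^2) / nl
  vh <- sum(wh * (codes - mh)^2) / nh
  f <- if ((vl + vh) == 0) { if (ml == mh) 0 else Inf } else (ml - mh)^2 / (vl + vh)

  structure(
    list(item_id = xtab$item_id, auroc = auroc, fisher_f = f,
         n_low = nl, n_high = nh, policy = policy),
    class = "bq_discrim"
  )
}

#' @export
print.bq_discrim <- function(x, ...) {
  cat("<bq_discrim> ", x$item_id, ": AUROC = ", round(x$auroc, 3),
      ", F = ", round(x$fisher_f, 3), " (n = ", x$n_low, " low / ",
      x$n_high, " high)\n", sep = "")
  invisible(x)
}

#' Score every feature of an encoded dataset
#'
#' Per feature: drop missing values, compute the Fisher score and rank
#' AUROC against the high/low label. Features are ranked by AUROC
#' descending, ties broken by F descending then by feature order.
#'
#' @param encoded a [bq_encode()] result
#' @return data frame with columns `item_id`, `auroc`, `fisher_f`,
#'   `n_low`, `n_high`, sorted by rank
#' @export
bq_score_all <- function(encoded) {
  stopifnot(inherits(encoded, "bq_encoded"), nrow(encoded$x) > 0)
  lab <- encoded$labels
  rows <- lapply(seq_along(encoded$features), function(j) {
    v <- encoded$x[, j]
    keep <- !is.na(v)
    xl <- v[keep & lab == "low"]; xh <- v[keep & lab == "high"]
    data.frame(item_id = encoded$features[j],
               auroc = bq_rank_auroc(xl, xh),
               fisher_f = bq_fisher_score(xl, xh),
               n_low = length(xl), n_high = length(xh),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$auroc, -out$fisher_f, seq_len(nrow(out))), , drop = FALSE]
}
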