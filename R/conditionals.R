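# Class-conditional response tables: per-item level counts in the low-risk
# (n = 311) and high-risk (n = 76) groups of the source survey. These are the
# calibration targets of the synthetic-cohort generator. A few printed cells
# are internally inconsistent in the source table; they are transcribed as
# printed and carried with a flag rather than silently repaired.

#' Build a class-conditional table
#'
#' @param item_id item identifier present in the dictionary
#' @param counts_low,counts_high named integer vectors of level counts per
#'   class (names must be legal levels of the item, in any order)
#' @param missing_low,missing_high structurally missing counts per class
#' @param flags character notes about known transcription inconsistencies
#' @param dict item dictionary used to validate level names
#' @return object of class `bq_conditional`
#' @export
bq_conditional <- function(item_id, counts_low, counts_high,
                           missing_low = 0L, missing_high = 0L,
                           flags = character(),
                           dict = bq_item_dictionary()) {
  it <- dict[[item_id]]
  if (is.null(it)) stop("unknown item: ", item_id)
  lv <- it$levels
  stopifnot(all(names(counts_low) %in% lv), all(names(counts_high) %in% lv),
            all(counts_low >= 0), all(counts_high >= 0),
            missing_low >= 0, missing_high >= 0)
  cl <- stats::setNames(rep(0L, length(lv)), lv)
  ch <- cl
  cl[names(counts_low)] <- as.integer(counts_low)
  ch[names(counts_high)] <- as.integer(counts_high)
  if (sum(cl) + sum(ch) == 0) stop("all counts zero for ", item_id)
  tot_low <- sum(cl) + missing_low
  tot_high <- sum(ch) + missing_high
  if (!length(flags)) {
    if (tot_low != 311) flags <- c(flags, paste0("low column sums to ", tot_low, ", not 311"))
    if (tot_high != 76) flags <- c(flags, paste0("high column sums to ", tot_high, ", not 76"))
  }
  structure(
    list(item_id = item_id, levels = lv, counts_low = cl, counts_high = ch,
         missing_low = as.integer(missing_low),
         missing_high = as.integer(missing_high), flags = flags),
    class = "bq_conditional"
  )
}

#' Default class-conditional tables from the published survey
#'
#' Transcribes the per-item response counts of the low-risk (n = 311) and
#' high-risk (n = 76) groups for the ten BQ items (including the structural
#' missingness of the follow-up items B2 and B9) and the 38 extended items.
#' These counts parameterize [bq_generate_cohort()].
#'
#' Three cells are flagged as inconsistent in the source: the asthma item's
#' low column sums to 321, one attention item's low column sums to 325, and
#' the stimulant item's high "Almost every day" count is reconstructed from
#' its printed percentage (28% of 76 = 21).
#'
#' @param extended include the extended items (default `TRUE`)
#' @param dict item dictionary
#' @return named list of [bq_conditional()] objects
#' @export
bq_default_conditionals <- function(extended = TRUE, dict = bq_item_dictionary()) {
  f5 <- .lv_freq5
  s5 <- .lv_symptom5
  i6 <- .lv_interfere6
  cc <- function(lv, x) stats::setNames(x, lv)
  out <- list(
    bq_conditional("B1", cc(.lv_noyes, c(164, 83, 64)), cc(.lv_noyes, c(2, 2, 72)), dict = dict),
    bq_conditional("B2",
      cc(dict$B2$levels, c(213, 5, 11, 8)), cc(dict$B2$levels, c(35, 8, 12, 21)),
      missing_low = 74, missing_high = 0, dict = dict),
    bq_conditional("B3", cc(f5, c(173, 46, 41, 20, 31)), cc(f5, c(1, 5, 9, 13, 48)), dict = dict),
    bq_conditional("B4", cc(.lv_noyes, c(172, 71, 68)), cc(.lv_noyes, c(9, 6, 61)), dict = dict),
    bq_conditional("B5", cc(f5, c(299, 3, 3, 3, 3)), cc(f5, c(41, 10, 11, 8, 6)), dict = dict),
    bq_conditional("B6", cc(f5, c(117, 73, 68, 23, 30)), cc(f5, c(8, 9, 9, 16, 34)), dict = dict),
    bq_conditional("B7", cc(f5, c(76, 82, 88, 33, 32)), cc(f5, c(8, 6, 11, 17, 34)), dict = dict),
    bq_conditional("B8", cc(c("No", "Yes"), c(284, 27)), cc(c("No", "Yes"), c(58, 18)), dict = dict),
    bq_conditional("B9", cc(f5, c(212, 15, 5, 1, 0)), cc(f5, c(37, 7, 5, 2, 3)),
                   missing_low = 78, missing_high = 22, dict = dict),
    bq_conditional("B10", cc(.lv_noyes, c(284, 11, 16)), cc(.lv_noyes, c(33, 4, 39)), dict = dict)
  )
  if (extended) {
    ext <- list(
      bq_conditional("Q1", cc(dict$Q1$levels, c(247, 64)), cc(dict$Q1$levels, c(46, 30)), dict = dict),
      bq_conditional("Q2", cc(dict$Q2$levels, c(103, 75, 68, 62, 3)),
                     cc(dict$Q2$levels, c(12, 13, 32, 16, 3)), dict = dict),
      bq_conditional("Q3", cc(dict$Q3$levels, c(6, 179, 73, 53)),
                     cc(dict$Q3$levels, c(2, 25, 27, 22)), dict = dict),
      bq_conditional("Q4", cc(dict$Q4$levels, c(81, 190, 40)),
                     cc(dict$Q4$levels, c(23, 39, 14)), dict = dict),
      bq_conditional("Q5", cc(dict$Q5$levels, c(135, 18, 158)),
                     cc(dict$Q5$levels, c(29, 11, 36)), dict = dict),
      bq_conditional("Q6", cc(dict$Q6$levels, c(282, 22, 1, 6)),
                     cc(dict$Q6$levels, c(63, 5, 6, 2)), dict = dict),
      bq_conditional("Q7", cc(dict$Q7$levels, c(61, 20, 167, 34, 29)),
                     cc(dict$Q7$levels, c(24, 7, 31, 8, 6)), dict = dict),
      bq_conditional("Q8", cc(dict$Q8$levels, c(118, 32, 29, 30, 27, 37, 38)),
                     cc(dict$Q8$levels, c(12, 15, 2, 13, 15, 8, 11)), dict = dict),
      bq_conditional("Q9", cc(dict$Q9$levels, c(284, 27)), cc(dict$Q9$levels, c(72, 4)), dict = dict),
      bq_conditional("Q10", cc(dict$Q10$levels, c(129, 182)), cc(dict$Q10$levels, c(33, 43)), dict = dict),
      bq_conditional("Q11", cc(c("Yes", "No"), c(193, 118)), cc(c("Yes", "No"), c(42, 34)), dict = dict),
      bq_conditional("Q12", cc(c("Yes", "No"), c(2, 309)), cc(c("Yes", "No"), c(18, 58)), dict = dict),
      bq_conditional("Q13", cc(c("No", "Yes"), c(265, 46)), cc(c("No", "Yes"), c(60, 16)), dict = dict),
      bq_conditional("Q14", cc(c("No", "Yes"), c(272, 39)), cc(c("No", "Yes"), c(48, 28)), dict = dict),
      bq_conditional("Q15", cc(c("No", "Yes"), c(310, 1)), cc(c("No", "Yes"), c(71, 5)), dict = dict),
      bq_conditional("Q16", cc(c("No", "Yes"), c(305, 6)), cc(c("No", "Yes"), c(65, 11)), dict = dict),
      bq_conditional("Q17", cc(c("No", "Yes"), c(309, 2)), cc(c("No", "Yes"), c(73, 3)), dict = dict),
      bq_conditional("Q18", cc(c("No", "Yes"), c(207, 104)), cc(c("No", "Yes"), c(35, 41)), dict = dict),
      bq_conditional("Q19", cc(c("No", "Yes"), c(239, 72)), cc(c("No", "Yes"), c(38, 36)),
                     flags = "high column sums to 74 as printed (expected 76; both cells print 50%)",
                     dict = dict),
      bq_conditional("Q20", cc(c("No", "Yes"), c(310, 1)), cc(c("No", "Yes"), c(70, 6)), dict = dict),
      bq_conditional("Q21", cc(c("No", "Yes"), c(291, 30)), cc(c("No", "Yes"), c(58, 18)),
                     flags = "low column sums to 321 as printed (expected 311)", dict = dict),
      bq_conditional("Q22", cc(c("No", "Yes"), c(303, 8)), cc(c("No", "Yes"), c(68, 8)), dict = dict),
      bq_conditional("Q23", cc(c("No", "Yes"), c(308, 3)), cc(c("No", "Yes"), c(71, 5)), dict = dict),
      bq_conditional("Q24", cc(c("No", "Yes"), c(307, 4)), cc(c("No", "Yes"), c(71, 5)), dict = dict),
      bq_conditional("Q25", cc(c("No", "Yes"), c(280, 31)), cc(c("No", "Yes"), c(60, 16)), dict = dict),
      bq_conditional("Q26", cc(c("No", "Yes"), c(305, 6)), cc(c("No", "Yes"), c(74, 2)), dict = dict),
      bq_conditional("Q27", cc(s5, c(284, 20, 3, 3, 1)), cc(s5, c(58, 8, 5, 3, 2)), dict = dict),
      bq_conditional("Q28", cc(s5, c(152, 117, 33, 7, 2)), cc(s5, c(22, 22, 14, 11, 7)), dict = dict),
      bq_conditional("Q29", cc(s5, c(195, 89, 16, 8, 3)), cc(s5, c(36, 16, 15, 6, 3)), dict = dict),
      bq_conditional("Q30", cc(s5, c(132, 62, 29, 69, 19)), cc(s5, c(21, 12, 13, 21, 9)),
                     flags = "high 'Almost every day' count reconstructed from printed 28% of 76",
                     dict = dict),
      bq_conditional("Q31", cc(i6, c(138, 112, 48, 8, 4, 1)), cc(i6, c(30, 15, 15, 12, 3, 1)), dict = dict),
      bq_conditional("Q32", cc(i6, c(133, 104, 58, 9, 6, 1)), cc(i6, c(15, 27, 17, 11, 5, 1)), dict = dict),
      bq_conditional("Q33", cc(s5, c(189, 92, 22, 4, 4)), cc(s5, c(34, 17, 15, 7, 3)), dict = dict),
      bq_conditional("Q34", cc(s5, c(169, 106, 19, 14, 3)), cc(s5, c(26, 23, 14, 7, 6)), dict = dict),
      bq_conditional("Q35", cc(s5, c(180, 105, 17, 6, 17)), cc(s5, c(26, 25, 13, 10, 2)),
                     flags = "low column sums to 325 as printed (expected 311)", dict = dict),
      bq_conditional("Q36", cc(s5, c(208, 82, 9, 12, 0)), cc(s5, c(41, 15, 10, 8, 2)), dict = dict),
      bq_conditional("Q37", cc(s5, c(165, 115, 16, 11, 4)), cc(s5, c(26, 25, 12, 11, 2)), dict = dict),
      bq_conditional("Q38", cc(s5, c(79, 99, 69, 61, 3)), cc(s5, c(5, 23, 18, 27, 3)), dict = dict)
    )
    out <- c(out, ext)
  }
  names(out) <- vapply(out, `[[`, "", "item_id")
  out
}

#' @export
print.bq_conditional <- function(x, ...) {
  cat("<bq_conditional> ", x$item_id, "\n", sep = "")
  m <- cbind(low = x$counts_low, high = x$counts_high)
  if (x$missing_low + x$missing_high > 0) {
    m <- rbind(m, `(missing)` = c(x$missing_low, x$missing_high))
  }
  print(m)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
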