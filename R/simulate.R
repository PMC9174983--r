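# Synthetic survey cohorts. Each subject draws a latent high/low class
# (Bernoulli at the study prevalence), then item responses from the
# class-conditional tables; the usable risk label is always recomputed by
# the BQ scorer so the deterministic label-feature relationship of the real
# instrument is preserved. Items are sampled independently within class
# (only class-conditional marginals are published), except for the B1->B2
# and B8->B9 skip-logic couplings.

.bmi_bins <- matrix(c(18, 18.5, 18.5, 25, 25, 30, 30, 46),
                    ncol = 2, byrow = TRUE)

#' Generator configuration
#'
#' @param n_subjects cohort size (default 387, the study's respondent count)
#' @param prevalence latent high-class probability (default 0.20, the
#'   study's high-risk proportion)
#' @param conditionals class-conditional tables, see
#'   [bq_default_conditionals()]
#' @param skip_logic enforce B1->B2 and B8->B9 skip-logic consistency
#' @param extended also generate the 38 extended items
#' @param seed integer RNG seed
#' @return object of class `bq_generator_config`
#' @export
bq_generator_config <- function(n_subjects = 387, prevalence = 0.20,
                                conditionals = bq_default_conditionals(),
                                skip_logic = TRUE, extended = TRUE,
                                seed = 1L) {
  stopifnot(n_subjects >= 0, length(prevalence) == 1)
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  structure(
    list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
         conditionals = conditionals, skip_logic = isTRUE(skip_logic),
         extended = isTRUE(extended), seed = as.integer(seed)),
    class = "bq_generator_config"
  )
}

# Draw n levels (or NA for the missing mass) from one conditional column.
sample_levels <- function(n, counts, missing = 0) {
  if (n == 0) return(character(0))
  pool <- c(names(counts), NA_character_)
  w <- c(as.numeric(counts), missing)
  keep <- w > 0
  sample(pool[keep], n, replace = TRUE, prob = w[keep])
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws a cohort whose class-conditional item frequencies match the
#' configured tables. BMI is drawn by sampling the BMI group (underweight /
#' normal / overweight / obese) from its conditional and then uniformly
#' within the group's range (18-46 kg/m^2 overall); the `Q3` column is
#' derived from the drawn BMI so the two stay consistent. With
#' `skip_logic = TRUE`, subjects answering "No" to B1 have B2 structurally
#' missing, and B9 (frequency of nodding off while driving) is kept
#' consistent with B8: full conditional when B8 = "Yes", otherwise only
#' "Never or almost never" or missing, in their configured proportions.
#'
#' The returned data frame carries the latent class as attribute
#' `"latent"` (diagnostics only) and the configuration as `"config"`. The
#' analysis label is *not* the latent class: compute it with
#' [bq_classify_risk()], or take the convenience attribute `"label"`.
#'
#' @param config a [bq_generator_config()]
#' @param dict item dictionary
#' @return data frame (`subject_id`, `B1`..`B10`, `bmi`, and `Q1`..`Q38`
#'   when extended) with attributes `latent`, `label`, `config`
#' @examples
#' coh <- bq_generate_cohort(bq_generator_config(n_subjects = 50, seed = 7))
#' table(attr(coh, "label"))
#' @export
bq_generate_cohort <- function(config = bq_generator_config(),
                               dict = bq_item_dictionary(config$extended)) {
  n <- config$n_subjects
  cond <- config$conditionals
  set.seed(config$seed)
  latent <- factor(ifelse(stats::runif(n) < config$prevalence, "high", "low"),
                   levels = c("low", "high"))
  idx_low <- which(latent == "low")
  idx_high <- which(latent == "high")

  draw_item <- function(cd, restrict = NULL) {
    out <- character(n)
    for (cls in c("low", "high")) {
      idx <- if (cls == "low") idx_low else idx_high
      cnt <- if (cls == "low") cd$counts_low else cd$counts_high
      mis <- if (cls == "low") cd$missing_low else cd$missing_high
      if (!is.null(restrict)) {
        cnt <- cnt[names(cnt) %in% restrict]
        if (!"(missing)" %in% restrict) mis <- 0
      }
      out[idx] <- sample_levels(length(idx), cnt, mis)
    }
    out
  }

  items <- setdiff(names(cond), c("Q3", if (config$skip_logic) c("B2", "B9")))
  cohort <- stats::setNames(
    as.data.frame(lapply(items, function(id) draw_item(cond[[id]])),
                  stringsAsFactors = FALSE),
    items)

  if (config$skip_logic && "B2" %in% names(cond)) {
    # follow-up sampled from answered levels only; structurally missing
    # whenever the parent denies snoring
    b2 <- draw_item(cond[["B2"]], restrict = names(cond[["B2"]]$counts_low))
    b2[cohort$B1 == "No"] <- NA
    cohort$B2 <- b2
  }
  if (config$skip_logic && "B9" %in% names(cond)) {
    b9 <- character(n)
    yes <- !is.na(cohort$B8) & cohort$B8 == "Yes"
    full <- draw_item(cond[["B9"]])
    never <- draw_item(cond[["B9"]], restrict = c("Never or almost never", "(missing)"))
    b9[yes] <- full[yes]
    b9[!yes] <- never[!yes]
    cohort$B9 <- b9
  }

  # BMI from its group conditional, uniform within group range
  if ("Q3" %in% names(cond)) {
    grp <- draw_item(cond[["Q3"]])
    gi <- match(grp, cond[["Q3"]]$levels)
    bmi <- .bmi_bins[gi, 1] + stats::runif(n) * (.bmi_bins[gi, 2] - .bmi_bins[gi, 1])
    cohort$bmi <- round(bmi, 1)
    if (config$extended) {
      cohort$Q3 <- cond[["Q3"]]$levels[
        findInterval(cohort$bmi, c(-Inf, 18.5, 25, 30, Inf))]
    } else {
      cohort$Q3 <- NULL
    }
  }

  ord <- intersect(c(paste0("B", 1:10), "bmi", paste0("Q", 1:38)), names(cohort))
  cohort <- cohort[, ord, drop = FALSE]
  cohort <- cbind(subject_id = sprintf("S%05d", seq_len(n)), cohort,
                  stringsAsFactors = FALSE)
  if (!config$extended) cohort[grep("^Q", names(cohort))] <- NULL

  attr(cohort, "latent") <- latent
  attr(cohort, "label") <- if (n > 0) bq_classify_risk(cohort, bq_item_dictionary())
                           else factor(character(), levels = c("low", "high"))
  attr(cohort, "config") <- config
  cohort
}

#' Add completely-at-random missingness
#'
#' Blanks each listed item independently at the given per-item rate, on top
#' of any structural (skip-logic) missingness already present.
#'
#' @param cohort subject-level data frame
#' @param rates named numeric vector, item id -> missingness probability
#' @param seed integer RNG seed
#' @return the cohort with additional `NA` entries
#' @export
bq_apply_missingness <- function(cohort, rates, seed = 1L) {
  stopifnot(is.data.frame(cohort), !is.null(names(rates)))
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  set.seed(seed)
  for (id in names(rates)) {
    col <- if (id %in% names(cohort)) id else tolower(id)
    if (!col %in% names(cohort)) stop("unknown item: ", id)
    hit <- stats::runif(nrow(cohort)) < rates[[id]]
    cohort[[col]][hit] <- NA
  }
  cohort
}
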