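# Deterministic BQ risk scoring: three symptom categories, high risk when
# two or more categories are positive. Missing answers never count as
# positive; category 3 uses the hypertension item and the BMI > 30 cut-off.

.positive_answer <- function(answers, item) {
  !is.na(answers) & answers %in% item$positive_levels
}

#' Score the three BQ symptom categories
#'
#' Category 1 (snoring, items B1-B5) is positive when at least two of its
#' items receive a positive symptom response; category 2 (daytime somnolence,
#' B6-B8) likewise with two of three; category 3 is positive when B10 is
#' "Yes" (history of high blood pressure) or BMI exceeds 30 kg/m^2. Missing
#' answers are simply unavailable: they never count as positive, and a
#' category is evaluated from whatever items were answered.
#'
#' @param cohort data frame with one row per subject: columns `B1`..`B10`
#'   holding response-level labels (or `NA`), and `bmi` (numeric, kg/m^2,
#'   `NA` allowed)
#' @param dict item dictionary (see [bq_item_dictionary()]); its
#'   `positive_levels` define the scoring rule and can be swapped for
#'   sensitivity analyses
#' @return data frame with logical columns `cat1_positive`, `cat2_positive`,
#'   `cat3_positive` and integer `positive_count`
#' @examples
#' rec <- data.frame(B1 = "Yes", B2 = NA, B3 = "Every day", B4 = "No",
#'                   B5 = "Never or almost never", B6 = "Never or almost never",
#'                   B7 = "Never or almost never", B8 = "No", B9 = NA,
#'                   B10 = "No", bmi = 22)
#' bq_score_categories(rec)
#' @export
bq_score_categories <- function(cohort, dict = bq_item_dictionary()) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  bad <- bq_validate_cohort(cohort, dict)
  if (nrow(bad)) {
    stop("invalid records: ", paste0(
      "row ", bad$row, " ", bad$item, ": ", bad$problem, collapse = "; "))
  }
  getcol <- function(id) {
    if (id %in% names(cohort)) as.character(cohort[[id]])
    else rep(NA_character_, nrow(cohort))
  }
  npos <- function(ids) {
    Reduce(`+`, lapply(ids, function(id) .positive_answer(getcol(id), dict[[id]])))
  }
  cat1 <- npos(c("B1", "B2", "B3", "B4", "B5")) >= 2
  cat2 <- npos(c("B6", "B7", "B8")) >= 2
  b10 <- .positive_answer(getcol("B10"), dict[["B10"]])
  bmi <- if ("bmi" %in% names(cohort)) cohort$bmi else rep(NA_real_, nrow(cohort))
  cat3 <- b10 | (!is.na(bmi) & bmi > 30)
  data.frame(
    cat1_positive = cat1, cat2_positive = cat2, cat3_positive = cat3,
    positive_count = as.integer(cat1) + as.integer(cat2) + as.integer(cat3)
  )
}

#' Classify subjects as high or low OSA risk
#'
#' A subject is at high risk when two or more of the three BQ categories are
#' positive. The rule is deterministic: identical answers always yield the
#' same label.
#'
#' @inheritParams bq_score_categories
#' @return factor with levels `low`, `high`, one element per row
#' @examples
#' rec <- data.frame(B1 = "Yes", B3 = "Every day", B4 = "Yes",
#'                   B6 = "Every day", B7 = "Every day", B10 = "No", bmi = 24)
#' bq_classify_risk(rec)
#' @export
bq_classify_risk <- function(cohort, dict = bq_item_dictionary()) {
  sc <- bq_score_categories(cohort, dict)
  factor(ifelse(sc$positive_count >= 2, "high", "low"), levels = c("low", "high"))
}

#' Ordinal encoding policy
#'
#' Fixes how response labels become numbers: each level takes its 0-based
#' index in the dictionary (instrument-printed) order, and "Do not know"
#' responses are either treated as missing (`"as_missing"`, the default used
#' for discrimination-score reproduction) or kept at their ordinal position
#' (`"as_middle"`; in the printed No / Do not know / Yes order that position
#' is literally the middle code).
#'
#' @param dontknow `"as_missing"` or `"as_middle"`
#' @return an object of class `bq_policy`
#' @export
bq_encoding_policy <- function(dontknow = c("as_missing", "as_middle")) {
  structure(list(dontknow = match.arg(dontknow)), class = "bq_policy")
}

# Numeric codes for one item's level labels under a policy. NA label -> NA.
encode_levels <- function(labels, item, policy) {
  codes <- match(labels, item$levels) - 1
  if (anyNA(codes[!is.na(labels)])) {
    bad <- unique(labels[!is.na(labels) & is.na(match(labels, item$levels))])
    stop("unknown level(s) for ", item$item_id, ": ", paste(bad, collapse = ", "))
  }
  if (policy$dontknow == "as_missing") {
    codes[!is.na(labels) & labels == "Do not know"] <- NA
  }
  as.numeric(codes)
}

decode_levels <- function(codes, item) {
  item$levels[as.integer(codes) + 1L]
}

#' Encode a cohort into a numeric feature matrix
#'
#' Converts level labels to ordinal codes under an encoding policy, carries
#' BMI as a continuous column, marks missing answers as `NA` (the missing
#' marker the boosted classifier handles natively), and recomputes the
#' high/low risk label with [bq_classify_risk()] — labels are never taken
#' from the input.
#'
#' @param cohort subject-level data frame (see [bq_score_categories()])
#' @param features character vector of item ids to encode; default the ten
#'   BQ items plus BMI
#' @param policy a [bq_encoding_policy()]
#' @param dict item dictionary
#' @return object of class `bq_encoded`: list with `x` (numeric matrix,
#'   subjects x features), `features`, `labels` (factor low/high) and
#'   `policy`
#' @export
bq_encode <- function(cohort, features = bq_item_ids(dict),
                      policy = bq_encoding_policy(), dict = bq_item_dictionary()) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0) stop("empty cohort")
  cols <- lapply(features, function(id) {
    it <- dict[[id]]
    if (is.null(it)) stop("unknown item: ", id)
    if (it$type == "numeric") {
      as.numeric(cohort[[tolower(id)]] %||% cohort[[id]])
    } else {
      vals <- if (id %in% names(cohort)) as.character(cohort[[id]])
              else rep(NA_character_, nrow(cohort))
      encode_levels(vals, it, policy)
    }
  })
  x <- do.call(cbind, cols)
  colnames(x) <- features
  structure(
    list(x = x, features = features,
         labels = bq_classify_risk(cohort, dict), policy = policy),
    class = "bq_encoded"
  )
}

#' Construct an encoded dataset from a matrix and labels
#'
#' Lightweight constructor for programmatic datasets (simulation studies,
#' planted-signal experiments) that bypasses the questionnaire dictionary.
#'
#' @param x numeric matrix, subjects x features (`NA` = missing)
#' @param labels factor or character with levels `low`, `high`
#' @param policy encoding policy to record
#' @return object of class `bq_encoded`
#' @export
bq_encoded <- function(x, labels, policy = bq_encoding_policy()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- factor(labels, levels = c("low", "high"))
  stopifnot(nrow(x) == length(labels), !anyNA(labels))
  structure(list(x = x, features = colnames(x), labels = labels,
                 policy = policy), class = "bq_encoded")
}

#' @export
print.bq_encoded <- function(x, ...) {
  cat("<bq_encoded> ", nrow(x$x), " subjects x ", ncol(x$x), " features (",
      sum(x$labels == "high"), " high / ", sum(x$labels == "low"), " low)\n",
      sep = "")
  invisible(x)
}

# Restrict an encoded dataset to rows and/or features.
encoded_subset <- function(enc, rows = NULL, features = NULL) {
  x <- enc$x
  labels <- enc$labels
  if (!is.null(rows)) {
    x <- x[rows, , drop = FALSE]
    labels <- labels[rows]
  }
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  structure(list(x = x, features = colnames(x), labels = labels,
                 policy = enc$policy), class = "bq_encoded")
}
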