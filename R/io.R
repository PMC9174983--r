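# Subject-level CSV input/output (labels or integer-codes dialect), report
# assembly, and JSON run manifests.

#' Read a subject-level cohort CSV
#'
#' One row per subject, header row, UTF-8. In the `"labels"` dialect cells
#' hold response-level labels; in `"codes"` they hold 0-based ordinal codes
#' in dictionary level order. Empty cells are missing. Rows failing
#' validation (illegal level or code, BMI outside 10-80) are rejected and
#' reported in the `"validation"` attribute; duplicated subject ids are an
#' error.
#'
#' @param path CSV file path
#' @param dialect `"labels"` or `"codes"`
#' @param dict item dictionary
#' @return validated cohort data frame with attribute `"validation"` (data
#'   frame of rejected rows and reasons)
#' @export
bq_read_cohort <- function(path, dialect = c("labels", "codes"),
                           dict = bq_item_dictionary()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  known <- c("subject_id", names(dict), "bmi")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "))
  if (!any(names(raw) %in% names(dict))) stop("no questionnaire columns found")
  if ("subject_id" %in% names(raw) && anyDuplicated(raw$subject_id)) {
    stop("duplicate subject_id values")
  }
  for (nm in names(raw)) raw[[nm]][raw[[nm]] == ""] <- NA

  for (id in intersect(names(raw), names(dict))) {
    it <- dict[[id]]
    if (it$type != "categorical") next
    if (dialect == "codes") {
      code <- suppressWarnings(as.integer(raw[[id]]))
      decoded <- rep(NA_character_, length(code))
      valid <- !is.na(code) & code >= 0 & code < length(it$levels)
      decoded[valid] <- it$levels[code[valid] + 1L]
      # keep unparseable non-empty cells as-is so validation flags them
      bad <- !is.na(raw[[id]]) & !valid
      decoded[bad] <- raw[[id]][bad]
      raw[[id]] <- decoded
    }
  }
  if ("bmi" %in% names(raw)) {
    bmi_chr <- raw$bmi
    raw$bmi <- suppressWarnings(as.numeric(bmi_chr))
    raw$bmi[!is.na(bmi_chr) & is.na(raw$bmi)] <- -1  # force validation failure
  }
  report <- bq_validate_cohort(raw, dict)
  if (nrow(report)) {
    keep <- setdiff(seq_len(nrow(raw)), unique(report$row))
    message(length(unique(report$row)), " row(s) rejected by validation")
    raw <- raw[keep, , drop = FALSE]
  }
  if (nrow(raw) == 0) stop("no valid rows after validation")
  attr(raw, "validation") <- report
  raw
}

#' Write a cohort CSV
#'
#' @param cohort subject-level data frame
#' @param path output path
#' @param dialect `"labels"` or `"codes"` (see [bq_read_cohort()])
#' @param dict item dictionary
#' @return `path`, invisibly
#' @export
bq_write_cohort <- function(cohort, path, dialect = c("labels", "codes"),
                            dict = bq_item_dictionary()) {
  dialect <- match.arg(dialect)
  out <- cohort
  if (dialect == "codes") {
    for (id in intersect(names(out), names(dict))) {
      it <- dict[[id]]
      if (it$type != "categorical") next
      out[[id]] <- match(as.character(out[[id]]), it$levels) - 1L
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the command, resolved configuration, seed(s), input/output paths,
#' package version and timestamp next to a run's outputs, so the run can be
#' reproduced exactly.
#'
#' @param path output JSON path
#' @param command short command name
#' @param config list of resolved configuration values (functions and
#'   classifier objects are recorded by name)
#' @param seed integer seed(s)
#' @param inputs,outputs character vectors of paths
#' @return `path`, invisibly
#' @export
bq_write_manifest <- function(path, command, config = list(), seed = NA,
                              inputs = character(), outputs = character()) {
  flatten <- function(x) {
    if (inherits(x, "bq_classifier")) return(x$name)
    if (is.function(x)) return("<function>")
    if (is.list(x)) return(lapply(x, flatten))
    x
  }
  manifest <- list(
    command = command, config = flatten(config), seed = seed,
    inputs = inputs, outputs = outputs,
    package = "bqscreen",
    version = as.character(utils::packageVersion("bqscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assemble a results report
#'
#' Writes the pipeline outputs as plain files under `dir`: the group summary
#' table (`summary.csv`), per-item discrimination scores (`discrim.csv`),
#' the AUROC-vs-cardinality curve (`curve.csv`), selection frequencies
#' (`selection_frequency.csv`), the co-occurrence matrix
#' (`cooccurrence.csv`) and a Markdown overview (`report.md`) that spells
#' out the chosen reduced questionnaire with the items' full wording.
#' Components that are absent from `results` are skipped; an empty bundle
#' produces a header-only report.
#'
#' @param results named list with any of: `summary` (data frame),
#'   `discrim` (data frame), `trace` (a `bq_selection_trace`),
#'   `aggregate` (a `bq_run_aggregate`), `cooccurrence` (matrix),
#'   `reduced` (character vector of item ids), `cv` (list mean/sd)
#' @param dir output directory (created if needed)
#' @param dict item dictionary (for question wording)
#' @return character vector of files written, invisibly
#' @export
bq_write_report <- function(results, dir, dict = bq_item_dictionary()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put_csv <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(results$summary)) put_csv(results$summary, "summary.csv")
  if (!is.null(results$discrim)) put_csv(results$discrim, "discrim.csv")
  if (!is.null(results$trace)) {
    put_csv(results$trace$curve, "curve.csv")
    put_csv(data.frame(rank = seq_along(results$trace$removal_order),
                       item_id = results$trace$removal_order),
            "removal_order.csv")
  }
  if (!is.null(results$aggregate)) {
    put_csv(data.frame(item_id = names(results$aggregate$frequency),
                       frequency = as.numeric(results$aggregate$frequency)),
            "selection_frequency.csv")
  }
  if (!is.null(results$cooccurrence)) {
    m <- as.data.frame(results$cooccurrence)
    m <- cbind(item_id = rownames(results$cooccurrence), m)
    put_csv(m, "cooccurrence.csv")
  }

  md <- c("# BQ screening analysis report", "")
  if (!is.null(results$reduced)) {
    md <- c(md, "## Reduced questionnaire", "")
    for (id in results$reduced) {
      it <- dict[[id]]
      md <- c(md,
              paste0("* **", id, "** — ", it$text),
              if (length(it$levels)) paste0("    - ", it$levels) else NULL)
    }
    md <- c(md, "")
  }
  if (!is.null(results$cv)) {
    md <- c(md, "## Cross-validated AUROC of the reduced set", "",
            sprintf("Mean AUROC %.3f (SD %.3f).", results$cv$mean, results$cv$sd), "")
  }
  if (length(written)) {
    md <- c(md, "## Files", "", paste0("* `", basename(written), "`"), "")
  }
  p <- file.path(dir, "report.md")
  writeLines(md, p)
  written <- c(written, p)
  invisible(written)
}
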