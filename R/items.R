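# The questionnaire instruments: the 10-item Berlin Questionnaire (BQ), the
# BMI pseudo-item it uses in category 3, and the 38 extended items covering
# demographics, work information, clinical status and daytime symptoms.

# shared level sets
.lv_freq5 <- c(
  "Never or almost never", "1-2 times a month", "1-2 times a week",
  "3-4 times a week", "Every day"
)
.lv_symptom5 <- c(
  "Never", "About once a week", "Two or three times a week",
  "Almost every day", "Several times a day"
)
.lv_interfere6 <- c("I have not had these problems", .lv_symptom5)
.lv_noyes <- c("No", "Do not know", "Yes")

.item <- function(id, text, levels, category = NA_integer_,
                  positive = character(), parent = NA_character_,
                  type = "categorical") {
  structure(
    list(item_id = id, text = text, levels = levels,
         category = as.integer(category), positive_levels = positive,
         parent_item = parent, type = type),
    class = "bq_item"
  )
}

#' The BQ and extended-item data dictionary
#'
#' Returns the full item dictionary: the ten Berlin Questionnaire items
#' `B1`-`B10` with their category memberships (1 = snoring, 2 = daytime
#' somnolence, 3 = hypertension/obesity), the continuous `BMI` pseudo-item,
#' and (optionally) the 38 extended items `Q1`-`Q38`. Response levels are
#' listed in their printed instrument order, which also fixes the ordinal
#' coding used throughout the package.
#'
#' The `positive_levels` of each scored BQ item follow the original BQ rule
#' table: a response counts as a positive symptom when it indicates frequent
#' symptoms (3-4 times a week or more for frequency items; the two loudest
#' levels for snoring loudness; "Yes" for the yes/no items). `B9` is the
#' skip-logic follow-up of `B8` and does not itself enter category scoring;
#' `B2` is the follow-up of `B1`.
#'
#' @param extended include the 38 extended items (default `TRUE`)
#' @return a named list of `bq_item` definitions, class `bq_dictionary`
#' @examples
#' dict <- bq_item_dictionary()
#' dict$B3$levels
#' dict$B10$category
#' @export
bq_item_dictionary <- function(extended = TRUE) {
  yn <- c("Yes", "No")
  ny <- c("No", "Yes")
  items <- list(
    .item("B1", "Do you snore?", .lv_noyes, 1, positive = "Yes"),
    .item("B2", "If you answered \"yes\", your snoring is:",
          c("Slightly louder than breathing", "As loud as talking",
            "Louder than talking",
            "Very loud - it can be heard from adjacent rooms"),
          1, positive = c("Louder than talking",
                          "Very loud - it can be heard from adjacent rooms"),
          parent = "B1"),
    .item("B3", "How often do you snore?", .lv_freq5, 1,
          positive = c("3-4 times a week", "Every day")),
    .item("B4", "Has your snoring ever bothered other people?", .lv_noyes, 1,
          positive = "Yes"),
    .item("B5", "Has anyone noticed that you stop breathing during your sleep?",
          .lv_freq5, 1,
          positive = c("1-2 times a week", "3-4 times a week", "Every day")),
    .item("B6", "How often do you feel tired or fatigued after your sleep?",
          .lv_freq5, 2, positive = c("3-4 times a week", "Every day")),
    .item("B7", "During your waking time, do you feel tired, fatigued or not up to par?",
          .lv_freq5, 2, positive = c("3-4 times a week", "Every day")),
    .item("B8", "Have you ever nodded off or fallen asleep while driving a vehicle?",
          .lv_noyes, 2, positive = "Yes"),
    .item("B9", "How often does this occur?", .lv_freq5, parent = "B8"),
    .item("B10", "Do you have high blood pressure?", .lv_noyes, 3,
          positive = "Yes"),
    .item("BMI", "Body mass index (kg/m^2)", character(), 3, type = "numeric")
  )
  if (extended) {
    ext <- list(
      .item("Q1", "Gender", c("Female", "Male")),
      .item("Q2", "Age (years)", c("21-30", "31-40", "41-50", "51-60", ">61")),
      .item("Q3", "BMI group (kg/m^2)",
            c("Underweight <18.5", "Normal weight 18.5-24.9",
              "Overweight 25-29.9", "Obese >=30")),
      .item("Q4", "Smoking", c("Yes", "No", "Ex-smoker")),
      .item("Q5", "Neck circumference (cm)",
            c("<43 men/41 women", ">=43 men/41 women", "Unknown")),
      .item("Q6", "Profession", c("Nurse", "Coordinator", "Executive", "Other")),
      .item("Q7", "Instruction level",
            c("Regional Diploma", "University Diploma", "Bachelor's degree",
              "Master degree", "Post-graduate")),
      .item("Q8", "Work experience (years)",
            c("1-5", "6-10", "11-15", "16-20", "21-25", "26-30", ">31")),
      .item("Q9", "Working hours", c("Full-time", "Part-time")),
      .item("Q10", "Work shift", c("Daily shift only", "24 h shift")),
      .item("Q11", "Work shift regularity", yn),
      .item("Q12", "Previous OSA diagnosis", yn),
      .item("Q13", "Hypo/hyperthyroidism", ny),
      .item("Q14", "Arrhythmias", ny),
      .item("Q15", "Transient ischemic attack or stroke", ny),
      .item("Q16", "Diabetes mellitus", ny),
      .item("Q17", "Presence of cerebrovascular diseases", ny),
      .item("Q18", "Anxiety", ny),
      .item("Q19", "Sleep disorders", ny),
      .item("Q20", "Chronic obstructive pulmonary disease (COPD)", ny),
      .item("Q21", "Asthma", ny),
      .item("Q22", "Frequent confusion or agitation", ny),
      .item("Q23", "Alcohol abuse", ny),
      .item("Q24", "Drug abuse", ny),
      .item("Q25", "Depression", ny),
      .item("Q26", "Craniofacial morphological alterations", ny),
      .item("Q27", "Have you ever fallen asleep during an activity (e.g., during work)?",
            .lv_symptom5),
      .item("Q28", "Did you have difficulty concentrating during an assignment?",
            .lv_symptom5),
      .item("Q29", "Did you have to force yourself to express yourself clearly?",
            .lv_symptom5),
      .item("Q30", "Have you had to use stimulants (coffee, tea, ginseng, etc.) to stay active?",
            .lv_symptom5),
      .item("Q31", "Have the problems reported in the previous questions interfered with your ability to work?",
            .lv_interfere6),
      .item("Q32", "Have the problems reported in the previous questions interfered with your social relationships?",
            .lv_interfere6),
      .item("Q33", "Have your reactions in everyday situations been slow?",
            .lv_symptom5),
      .item("Q34", "Did you have to try harder than usual to keep track of what you were doing?",
            .lv_symptom5),
      .item("Q35", "Did you have difficulty paying attention for a long time on a task?",
            .lv_symptom5),
      .item("Q36", "Have you had difficulty paying attention to multiple tasks at once (e.g., listening to a radio program while driving a car)?",
            .lv_symptom5),
      .item("Q37", "Did you have to work hard to pay attention and not make mistakes?",
            .lv_symptom5),
      .item("Q38", "Did you feel the need to doze off during the course of the day?",
            .lv_symptom5)
    )
    items <- c(items, ext)
  }
  names(items) <- vapply(items, `[[`, "", "item_id")
  structure(items, class = "bq_dictionary")
}

#' @export
print.bq_dictionary <- function(x, ...) {
  n_bq <- sum(grepl("^B", names(x))) - 1L  # BMI pseudo-item excluded
  cat("<bq_dictionary> ", n_bq, " BQ items + BMI + ",
      sum(grepl("^Q", names(x))), " extended items\n", sep = "")
  invisible(x)
}

#' Item identifiers by group
#'
#' @param dict a `bq_dictionary`
#' @param which `"bq"` (B1-B10), `"features"` (B1-B10 + BMI, the default
#'   machine-learning feature set), `"extended"` (Q1-Q38) or `"all"`
#' @return character vector of item ids
#' @export
bq_item_ids <- function(dict = bq_item_dictionary(),
                        which = c("features", "bq", "extended", "all")) {
  which <- match.arg(which)
  ids <- names(dict)
  switch(which,
    bq = grep("^B[0-9]+$", ids, value = TRUE),
    features = c(grep("^B[0-9]+$", ids, value = TRUE), "BMI"),
    extended = grep("^Q[0-9]+$", ids, value = TRUE),
    all = ids
  )
}

#' Export the data dictionary as JSON
#'
#' Writes one object per item with its id, wording, ordered levels, category
#' membership and positive (symptom-scored) levels, so external tools can
#' validate and encode subject files identically.
#'
#' @param path output file path
#' @param dict a `bq_dictionary`
#' @return `path`, invisibly
#' @export
bq_export_dictionary <- function(path, dict = bq_item_dictionary()) {
  out <- lapply(unclass(dict), function(it) {
    list(item_id = it$item_id, text = it$text, levels = it$levels,
         category = if (is.na(it$category)) NULL else it$category,
         positive_levels = it$positive_levels,
         parent_item = if (is.na(it$parent_item)) NULL else it$parent_item,
         type = it$type)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

# Validate one cohort data frame against the dictionary. Returns a data frame
# of row-level problems (empty when clean).
bq_validate_cohort <- function(cohort, dict = bq_item_dictionary()) {
  problems <- list()
  note <- function(row, item, msg) {
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, item = item, problem = msg, stringsAsFactors = FALSE)
  }
  for (id in intersect(names(cohort), names(dict))) {
    it <- dict[[id]]
    if (it$type != "categorical") next
    vals <- as.character(cohort[[id]])
    bad <- which(!is.na(vals) & !(vals %in% it$levels))
    for (r in bad) note(r, id, paste0("illegal level '", vals[r], "'"))
  }
  if ("bmi" %in% names(cohort)) {
    b <- cohort$bmi
    bad <- which(!is.na(b) & (b < 10 | b > 80))
    for (r in bad) note(r, "bmi", paste0("BMI out of range [10, 80]: ", b[r]))
  }
  if (length(problems)) do.call(rbind, problems)
  else data.frame(row = integer(), item = character(), problem = character(),
                  stringsAsFactors = FALSE)
}
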