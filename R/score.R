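#' Normalize answer codes
#'
#' Answers take one of three states: `"Y"` (yes), `"N"` (no), `"?"`
#' (unknown).  Input is case-insensitive and tolerant of common long
#' forms; empty strings and `NA` mean unknown.  Unknown is a distinct
#' state, not a synonym for no: it contributes no points and does not
#' count as answered.
#'
#' @param x character vector of raw answer codes.
#' @return character vector over `c("Y", "N", "?")`.
#' @export
normalize_answers <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("y", "yes")] <- "Y"
  out[raw %in% c("n", "no")] <- "N"
  out[raw %in% c("?", "", "u", "unk", "unknown", "na") | is.na(raw)] <- "?"
  if (anyNA(out)) {
    stop_input("unrecognized answer value(s): ",
               paste(unique(x[is.na(out)]), collapse = ", "),
               " (expected Y, N or ?)")
  }
  out
}

# answers: named character vector over {Y, N, ?}; names are question ids.
# Questions absent from `answers` are treated as unknown.
check_answer_ids <- function(answers, qset) {
  stray <- setdiff(names(answers), qset$id)
  if (length(stray)) {
    stop_input("answer(s) reference unknown question id(s): ",
               paste(stray, collapse = ", "))
  }
}

#' Score a single assessment
#'
#' The total score is the sum over questions of `points_yes` for yes
#' answers and `points_no` for no answers; unknown answers contribute
#' nothing.  Percent answered counts yes and no answers against the
#' full question count.
#'
#' @param answers named character vector of answers (`Y`/`N`/`?`,
#'   normalized via [normalize_answers()]); names are question ids from
#'   `qset`.  Questions with no entry are treated as unknown.
#' @param qset a [question_set()]; defaults to the shipped PRE set.
#' @param rule a [classification_rule()].
#' @param species optional species label carried into the result.
#' @return A one-row data frame: `species`, `total_score`,
#'   `percent_answered` (exact, not rounded), `risk_class`.
#' @examples
#' ans <- setNames(rep("Y", 19), pre_questions()$id)
#' score_assessment(ans)  # total score 23, Reject
#' @export
score_assessment <- function(answers, qset = pre_questions(),
                             rule = classification_rule(), species = NA_character_) {
  qset <- as_question_set(qset)
  answers <- stats::setNames(normalize_answers(answers), names(answers))
  if (length(answers) && is.null(names(answers))) {
    stop_input("answers must be named by question id")
  }
  check_answer_ids(answers, qset)
  a <- answers[match(qset$id, names(answers))]
  a[is.na(a)] <- "?"
  total <- sum(qset$points_yes[a == "Y"]) + sum(qset$points_no[a == "N"])
  pct <- 100 * sum(a %in% c("Y", "N")) / nrow(qset)
  data.frame(species = species, total_score = total, percent_answered = pct,
             risk_class = classify_score(total, rule),
             stringsAsFactors = FALSE)
}

#' Percent of questions answered
#'
#' @inheritParams score_assessment
#' @return Exact percentage in `[0, 100]`; use [round_half_up()] for the
#'   integer display convention.
#' @export
percent_answered <- function(answers, qset = pre_questions()) {
  qset <- as_question_set(qset)
  score_assessment(answers, qset)$percent_answered
}

# column names that are metadata rather than question answers
ASSESSMENT_META_COLS <- c("species", "family", "common_name", "growth_form",
                          "region", "status", "notes", "source")

#' Score a batch of assessments
#'
#' Takes an assessment table (one row per species; metadata columns plus
#' one column per question id holding `Y`/`N`/`?`) and returns scores,
#' answered percentages and risk classes.  Columns that are neither
#' recognized metadata (`species`, `family`, `common_name`,
#' `growth_form`, `region`, `status`, `notes`, `source`) nor question
#' ids of `qset` raise an error naming the offending headers.
#'
#' @param assessments data frame in the assessment-matrix dialect (see
#'   [read_assessments()]).
#' @param qset a [question_set()].
#' @param rule a [classification_rule()].
#' @param warn_below percentage; assessments answered below this level
#'   are flagged with a warning (low-information assessment).  The
#'   classification itself is never gated on evidence level.  Set to 0
#'   to disable.
#' @return Data frame with `species`, `total_score`, `percent_answered`
#'   (exact), `risk_class`, plus `status` when present in the input.
#' @examples
#' qs <- pre_questions()
#' df <- data.frame(species = "demo", q02 = "Y", q03 = "y")
#' score_assessments(df, qs)  # score 5
#' @export
score_assessments <- function(assessments, qset = pre_questions(),
                              rule = classification_rule(), warn_below = 80) {
  qset <- as_question_set(qset)
  if (!is.data.frame(assessments) || nrow(assessments) == 0L) {
    stop_input("assessments must be a non-empty data frame")
  }
  qcols <- intersect(names(assessments), qset$id)
  stray <- setdiff(names(assessments), c(ASSESSMENT_META_COLS, qset$id))
  if (length(stray)) {
    stop_input("unknown question column(s): ", paste(stray, collapse = ", "))
  }
  species <- if ("species" %in% names(assessments)) {
    as.character(assessments$species)
  } else {
    paste0("row_", seq_len(nrow(assessments)))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(assessments)), function(i) {
    ans <- stats::setNames(vapply(qcols, function(q) as.character(assessments[[q]][i]),
                                  character(1L)), qcols)
    score_assessment(ans, qset, rule, species = species[i])
  }))
  if ("status" %in% names(assessments)) {
    res$status <- parse_status(assessments$status)
  }
  low <- res$percent_answered < warn_below
  if (any(low)) {
    warning(sprintf("%d assessment(s) answered below %g%% of questions: %s",
                    sum(low), warn_below,
                    paste(res$species[low], collapse = ", ")),
            call. = FALSE)
  }
  rownames(res) <- NULL
  res
}

# tolerant parser for the binary species-status labels
parse_status <- function(x) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("invasive", "inv", "i", "knowninvasive")] <- "invasive"
  out[key %in% c("noninvasive", "non", "ni", "n", "knownnoninvasive")] <- "non_invasive"
  if (anyNA(out)) {
    stop_input("unrecognized status label(s): ",
               paste(unique(x[is.na(out)]), collapse = ", "),
               " (expected invasive / non_invasive)")
  }
  factor(out, levels = c("invasive", "non_invasive"))
}
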