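#' Read / write assessment matrices
#'
#' The assessment CSV dialect is UTF-8, comma-delimited with a header
#' row: metadata columns (`species` required for meaningful output;
#' optionally `family`, `common_name`, `growth_form`, `region`,
#' `status`, `notes`, `source`) followed by one column per question id
#' with values in `Y` / `N` / `?` (case-insensitive; empty cell means
#' unknown).  Columns that are neither metadata nor ids of `qset` raise
#' an error listing the offending headers.
#'
#' @param path file path.
#' @param qset a [question_set()] used to validate question columns.
#' @param assessments data frame to write.
#' @return `read_assessments()` returns the validated data frame with
#'   answer columns normalized; `write_assessments()` invisibly returns
#'   `path`.
#' @export
read_assessments <- function(path, qset = pre_questions()) {
  qset <- as_question_set(qset)
  if (!file.exists(path)) stop_input("input file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) stop_input("malformed CSV: ", conditionMessage(e)))
  if (nrow(df) == 0L) stop_input("empty input file: ", path)
  stray <- setdiff(names(df), c(ASSESSMENT_META_COLS, qset$id))
  if (length(stray)) {
    stop_input("unknown question column(s): ", paste(stray, collapse = ", "))
  }
  for (q in intersect(names(df), qset$id)) {
    ok <- vapply(df[[q]], function(v) {
      !inherits(tryCatch(normalize_answers(v), error = identity), "error")
    }, logical(1L), USE.NAMES = FALSE)
    if (!all(ok)) {
      stop_input("column '", q, "', data row(s) ",
                 paste(which(!ok), collapse = ", "),
                 ": unrecognized answer value(s): ",
                 paste(unique(df[[q]][!ok]), collapse = ", "))
    }
    df[[q]] <- normalize_answers(df[[q]])
  }
  df
}

#' @rdname read_assessments
#' @export
write_assessments <- function(assessments, path) {
  write.csv(assessments, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a score table
#'
#' Emits the scoring output dialect: `species`, `total_score`,
#' `percent_answered` (full precision), `risk_class`, plus any extra
#' columns present (e.g. `status`).
#'
#' @param scores data frame from [score_assessments()].
#' @param path file path.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a score table for validation
#'
#' Accepts the [write_scores()] dialect or any CSV carrying `status`
#' plus a score column (`total_score`, `score` or `pre_score`), with an
#' optional classification column checked for consistency.
#'
#' @param path file path.
#' @param rule a [classification_rule()].
#' @return A [labeled_outcomes()] data frame.
#' @export
read_outcomes <- function(path, rule = classification_rule()) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_input("empty input file: ", path)
  if (!"status" %in% names(df)) stop_input("missing required column: status")
  score_col <- intersect(c("total_score", "score", "pre_score"), names(df))
  if (!length(score_col)) {
    stop_input("missing a score column (total_score, score or pre_score)")
  }
  cls_col <- intersect(c("risk_class", "classification"), names(df))
  labeled_outcomes(df$species %||% paste0("row_", seq_len(nrow(df))),
                   df$status, df[[score_col[1L]]],
                   if (length(cls_col)) df[[cls_col[1L]]], rule)
}

#' Write a validation report as JSON
#'
#' Serializes a [validation_report()] with full-precision proportions,
#' the confusion counts under both naming conventions, and the policy.
#' `Inf` likelihood ratios are encoded as the string `"Inf"`.
#'
#' @param report a `pre_validation_report`.
#' @param path file path.
#' @export
write_validation_json <- function(report, path) {
  stopifnot(inherits(report, "pre_validation_report"))
  cn <- report$counts
  obj <- list(
    policy = report$policy,
    counts = list(TP = cn$TP, TN = cn$TN, FP = cn$FP, FN = cn$FN,
                  IT = cn$IT, NT = cn$NT, excluded_nfe = cn$excluded),
    counts_standard_naming = list(
      true_positive = cn$TN, false_negative = cn$FP,
      true_negative = cn$TP, false_positive = cn$FN),
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    overall_accuracy = report$overall_accuracy,
    sensitivity_pct = round_half_up(100 * report$sensitivity),
    specificity_pct = round_half_up(100 * report$specificity),
    overall_accuracy_pct = round_half_up(100 * report$overall_accuracy),
    likelihood_ratio = if (is.infinite(report$likelihood_ratio)) "Inf"
                       else report$likelihood_ratio)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
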