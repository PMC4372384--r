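#' Load a packaged published-data fixture
#'
#' The package ships plain-text transcriptions of the instrument's
#' published development and validation data:
#'
#' * `"table1"` — the 35 species (21 invasive, 14 non-invasive) of the
#'   initial 56-question screening, with each species' total score and
#'   percent of questions answered.
#' * `"table2"` — the 19 retained PRE questions with their printed
#'   two-tailed Fisher exact p-values, per-group answerability
#'   percentages and point values.
#' * `"table3"` — the validation species with status, classification and
#'   PRE score.  The printed table lists 56 invasive and 36 non-invasive
#'   rows while its own footnote totals (and every statistic derived
#'   from them) count 57 and 37; two placeholder rows flagged
#'   `source == "synthetic"` complete the fixture to the footnote totals
#'   (one invasive Reject, one non-invasive Accept, scored strictly
#'   inside the printed class score ranges).  Filter on
#'   `source == "printed"` for the rows exactly as published.
#'
#' File integrity is verified against a packaged MD5 manifest, guarding
#' against transcription drift.
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @return A data frame with typed columns (see Details above).
#' @examples
#' table(load_fixture("table3")$status)
#' @export
load_fixture <- function(name) {
  files <- c(table1 = "table1_56q_screening.csv",
             table2 = "table2_pre_questions.csv",
             table3 = "table3_pre_validation.csv")
  if (length(name) != 1L || !name %in% names(files)) {
    stop_input("unknown fixture name: ", paste(name, collapse = ", "),
               " (expected one of: ", paste(names(files), collapse = ", "), ")")
  }
  path <- system.file("extdata", files[[name]], package = "pretool", mustWork = TRUE)
  verify_fixture_checksum(files[[name]], path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  expected <- c(table1 = 35L, table2 = 19L, table3 = 94L)
  if (nrow(df) != expected[[name]]) {
    stop_input("fixture ", name, " has ", nrow(df), " rows, expected ",
               expected[[name]])
  }
  if ("status" %in% names(df)) df$status <- parse_status(df$status)
  df
}

verify_fixture_checksum <- function(file, path) {
  manifest_path <- system.file("extdata", "manifest.csv", package = "pretool",
                               mustWork = TRUE)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  expected <- manifest$md5[manifest$file == file]
  if (length(expected) != 1L) {
    stop_input("fixture not listed in checksum manifest: ", file)
  }
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, expected)) {
    stop_input("fixture checksum mismatch for ", file,
               " (transcription drift?): expected ", expected, ", got ", actual)
  }
  invisible(TRUE)
}

#' Published validation species as labeled outcomes
#'
#' Convenience accessor returning the table3 fixture in the form the
#' validation statistics consume, with the transcribed classification
#' verified against the score under the default rule.
#'
#' @param include_synthetic keep the two placeholder rows that complete
#'   the fixture to the published footnote totals (default `TRUE`; see
#'   [load_fixture()]).
#' @return A [labeled_outcomes()] data frame.
#' @examples
#' validation_report(table3_outcomes(), "count_as_error")
#' @export
table3_outcomes <- function(include_synthetic = TRUE) {
  t3 <- load_fixture("table3")
  if (!include_synthetic) t3 <- t3[t3$source == "printed", ]
  labeled_outcomes(t3$species, t3$status, t3$pre_score, t3$classification)
}
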