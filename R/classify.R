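#' Risk classes
#'
#' The three-way outcome of a PRE assessment, ordered by increasing risk:
#' Accept < Needs Further Evaluation < Reject.
#'
#' @format Character vector of the three class labels.
#' @export
risk_classes <- c("Accept", "Needs Further Evaluation", "Reject")

#' Three-way classification rule
#'
#' Scores strictly below `accept_below` are accepted (low invasive
#' risk), scores strictly above `reject_above` are rejected (high
#' invasive risk), and the closed band `[accept_below, reject_above]`
#' is referred for further evaluation.  The published PRE cutoffs are
#' accept `< 11`, needs-further-evaluation 11–13, reject `> 13`.
#'
#' @param accept_below scores below this are Accept (default 11).
#' @param reject_above scores above this are Reject (default 13).
#' @return A `pre_rule` list with the two cutoffs.
#' @examples
#' classify_score(c(10, 11, 13, 14), classification_rule())
#' @export
classification_rule <- function(accept_below = 11, reject_above = 13) {
  if (!is.numeric(accept_below) || !is.numeric(reject_above) ||
      length(accept_below) != 1L || length(reject_above) != 1L) {
    stop_input("classification cutoffs must be single numbers")
  }
  if (accept_below > reject_above + 1) {
    stop_input("invalid rule: accept_below must be <= reject_above + 1")
  }
  structure(list(accept_below = accept_below, reject_above = reject_above),
            class = "pre_rule")
}

#' Classify a score into the three-way outcome
#'
#' @param score numeric vector of non-negative total scores.
#' @param rule a [classification_rule()].
#' @return An ordered factor over [risk_classes].
#' @examples
#' classify_score(10)  # Accept
#' classify_score(13)  # Needs Further Evaluation
#' classify_score(14)  # Reject
#' @export
classify_score <- function(score, rule = classification_rule()) {
  if (!inherits(rule, "pre_rule")) rule <- do.call(classification_rule, as.list(rule))
  if (!is.numeric(score) || any(is.na(score))) {
    stop_input("scores must be numeric and non-missing")
  }
  if (any(score < 0)) stop_input("negative score: ", min(score))
  cls <- ifelse(score < rule$accept_below, risk_classes[1L],
                ifelse(score > rule$reject_above, risk_classes[3L],
                       risk_classes[2L]))
  factor(cls, levels = risk_classes, ordered = TRUE)
}

# tolerant parser for classification labels as they appear in data files
parse_risk_class <- function(x) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  map <- c(accept = 1L, needsfurtherevaluation = 2L, nfe = 2L, reject = 3L)
  idx <- map[key]
  if (any(is.na(idx))) {
    stop_input("unrecognized risk class label(s): ",
               paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  factor(risk_classes[idx], levels = risk_classes, ordered = TRUE)
}
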