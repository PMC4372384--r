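#' Assemble labeled outcomes for validation
#'
#' A labeled outcome joins a species' known status (invasive /
#' non-invasive) with its PRE score and three-way risk class.  When the
#' class is supplied (e.g. transcribed from a published table) it is
#' checked for consistency with the score under the active rule.
#'
#' @param species character vector of species labels.
#' @param status status labels (invasive / non_invasive, tolerant).
#' @param score numeric vector of total scores.
#' @param risk_class optional vector of class labels; recomputed from
#'   `score` when omitted, verified against it when present.
#' @param rule a [classification_rule()].
#' @return Data frame `species`, `status`, `score`, `risk_class` of
#'   class `pre_outcomes`.
#' @export
labeled_outcomes <- function(species, status, score, risk_class = NULL,
                             rule = classification_rule()) {
  status <- parse_status(status)
  if (!is.numeric(score) || anyNA(score)) stop_input("scores must be numeric")
  computed <- classify_score(score, rule)
  if (!is.null(risk_class)) {
    given <- parse_risk_class(risk_class)
    bad <- which(given != computed)
    if (length(bad)) {
      stop_input("risk class inconsistent with score under the active rule for: ",
                 paste(species[bad], collapse = ", "))
    }
  }
  out <- data.frame(species = as.character(species), status = status,
                    score = score, risk_class = computed,
                    stringsAsFactors = FALSE)
  class(out) <- c("pre_outcomes", "data.frame")
  out
}

as_outcomes <- function(x, rule = classification_rule()) {
  if (inherits(x, "pre_outcomes")) return(x)
  if (is.data.frame(x) && all(c("status", "score") %in% names(x))) {
    return(labeled_outcomes(x$species %||% paste0("row_", seq_len(nrow(x))),
                            x$status, x$score, x$risk_class, rule))
  }
  stop_input("expected labeled outcomes with 'status' and 'score' columns")
}

#' Confusion counts under a needs-further-evaluation policy
#'
#' Tallies the validation table's cells using its published label
#' convention: `TN` counts invasive species correctly classified Reject,
#' `TP` counts non-invasive species correctly classified Accept.  The
#' indeterminate ("needs further evaluation", NFE) outcomes are handled
#' by one of two policies:
#'
#' * `"count_as_error"` — an invasive species not rejected counts into
#'   `FP` and a non-invasive species not accepted counts into `FN`;
#'   `IT`/`NT` are the full class totals.
#' * `"exclude"` — NFE species are removed from all counts and totals.
#'   Outright misclassifications (invasive Accept, non-invasive Reject)
#'   still count as `FP`/`FN`: they are never excludable.
#'
#' Note this swaps positive/negative naming relative to the usual
#' epidemiological convention (where the invader would be the
#' "positive"); [print.pre_validation_report()] shows both namings.
#'
#' @param outcomes a [labeled_outcomes()] data frame.
#' @param policy `"count_as_error"` or `"exclude"`.
#' @return A `pre_confusion` list: `TP`, `TN`, `FP`, `FN`, `IT`, `NT`,
#'   `excluded`, `policy`.
#' @export
confusion_counts <- function(outcomes, policy = c("count_as_error", "exclude")) {
  policy <- match.arg(policy)
  outcomes <- as_outcomes(outcomes)
  if (nrow(outcomes) == 0L) stop_input("no outcomes supplied")
  if (length(unique(outcomes$status)) < 2L) {
    stop_stat("both invasive and non-invasive species are required")
  }
  inv <- outcomes[outcomes$status == "invasive", ]
  non <- outcomes[outcomes$status == "non_invasive", ]
  nfe <- risk_classes[2L]
  excluded <- 0L
  if (policy == "exclude") {
    excluded <- sum(outcomes$risk_class == nfe)
    inv <- inv[inv$risk_class != nfe, ]
    non <- non[non$risk_class != nfe, ]
  }
  counts <- list(
    TN = sum(inv$risk_class == "Reject"),
    FP = sum(inv$risk_class != "Reject"),
    TP = sum(non$risk_class == "Accept"),
    FN = sum(non$risk_class != "Accept"),
    IT = nrow(inv), NT = nrow(non),
    excluded = excluded, policy = policy)
  structure(counts, class = "pre_confusion")
}

#' Accuracy statistics from confusion counts
#'
#' Computes, under the published label convention, sensitivity (accuracy
#' for invasive species) `TN / (TN + FP)`, specificity (accuracy for
#' non-invasive species) `TP / (TP + FN)` and overall accuracy
#' `(TP + TN) / (IT + NT)`, as exact proportions.
#'
#' @param counts a [confusion_counts()] result.
#' @return List with `sensitivity`, `specificity`, `overall_accuracy`
#'   (proportions in `[0, 1]`).
#' @export
accuracy_metrics <- function(counts) {
  stopifnot(inherits(counts, "pre_confusion"))
  if (counts$IT == 0L) stop_stat("no invasive species enter the computation")
  if (counts$NT == 0L) stop_stat("no non-invasive species enter the computation")
  list(sensitivity = counts$TN / (counts$TN + counts$FP),
       specificity = counts$TP / (counts$TP + counts$FN),
       overall_accuracy = (counts$TP + counts$TN) / (counts$IT + counts$NT))
}

#' Likelihood ratio of the screening instrument
#'
#' `LR = (TP / IT) / (FP / NT)`: the ratio of the correct-accept
#' proportion among non-invaders to the not-rejected proportion among
#' invaders (published label convention).  Base-rate independent; 1
#' means no predictive capability.  When `FP = 0` the ratio is
#' `+Inf` (perfect screen); when both `TP` and `FP` are 0 it is
#' undefined and an error is raised.
#'
#' @param counts a [confusion_counts()] result.
#' @return Positive number or `Inf`.
#' @export
likelihood_ratio <- function(counts) {
  stopifnot(inherits(counts, "pre_confusion"))
  if (counts$IT == 0L || counts$NT == 0L) {
    stop_stat("likelihood ratio needs both status groups")
  }
  if (counts$TP == 0L && counts$FP == 0L) {
    stop_stat("likelihood ratio undefined: TP = FP = 0")
  }
  if (counts$FP == 0L) return(Inf)
  (counts$TP / counts$IT) / (counts$FP / counts$NT)
}

#' Full validation report
#'
#' Convenience wrapper assembling [confusion_counts()],
#' [accuracy_metrics()] and [likelihood_ratio()] for a labeled,
#' classified species set under one NFE policy.
#'
#' @inheritParams confusion_counts
#' @return A `pre_validation_report` list: `counts`, `sensitivity`,
#'   `specificity`, `overall_accuracy`, `likelihood_ratio`, `policy`.
#' @examples
#' t3 <- load_fixture("table3")
#' validation_report(labeled_outcomes(t3$species, t3$status, t3$pre_score),
#'                   policy = "count_as_error")
#' @export
validation_report <- function(outcomes, policy = c("count_as_error", "exclude")) {
  policy <- match.arg(policy)
  counts <- confusion_counts(outcomes, policy)
  m <- accuracy_metrics(counts)
  structure(c(list(counts = counts), m,
              list(likelihood_ratio = likelihood_ratio(counts), policy = policy)),
            class = "pre_validation_report")
}

#' @export
print.pre_confusion <- function(x, ...) {
  cat(sprintf("Confusion counts (policy: %s%s)\n", x$policy,
              if (x$excluded > 0) sprintf(", %d NFE species excluded", x$excluded) else ""))
  cat(sprintf("  TN (invasive rejected)        %4d   [std. naming: true positive]\n", x$TN))
  cat(sprintf("  FP (invasive not rejected)    %4d   [std. naming: false negative]\n", x$FP))
  cat(sprintf("  TP (non-invasive accepted)    %4d   [std. naming: true negative]\n", x$TP))
  cat(sprintf("  FN (non-invasive not accepted)%4d   [std. naming: false positive]\n", x$FN))
  cat(sprintf("  IT %d invasive, NT %d non-invasive\n", x$IT, x$NT))
  invisible(x)
}

#' @export
print.pre_validation_report <- function(x, ...) {
  print(x$counts)
  pct <- function(p) sprintf("%g%%", round_half_up(100 * p))
  cat(sprintf("  Sensitivity (invasive accuracy)     %s (%.4f)\n",
              pct(x$sensitivity), x$sensitivity))
  cat(sprintf("  Specificity (non-invasive accuracy) %s (%.4f)\n",
              pct(x$specificity), x$specificity))
  cat(sprintf("  Overall accuracy                    %s (%.4f)\n",
              pct(x$overall_accuracy), x$overall_accuracy))
  cat(sprintf("  Likelihood ratio                    %s\n",
              if (is.infinite(x$likelihood_ratio)) "Inf"
              else sprintf("%.2f", round_half_up(x$likelihood_ratio, 2))))
  invisible(x)
}
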