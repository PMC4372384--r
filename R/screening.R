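#' Build a 2x2 contingency table for one question
#'
#' Cross-tabulates species status (invasive / non-invasive) against the
#' yes/no answer to one question.  Unknown answers have no cell and are
#' dropped; the number dropped is reported.
#'
#' @param status vector of species status labels (see levels of
#'   [parse_status] — "invasive" / "non_invasive", tolerant parsing).
#' @param answers character vector of answers, same length as `status`.
#' @return List with `table` (2x2 integer matrix, rows invasive /
#'   non_invasive, columns yes / no) and `dropped` (count of unknown
#'   answers excluded).
#' @examples
#' build_contingency(rep(c("invasive", "non_invasive"), each = 4),
#'                   c("Y", "Y", "?", "N", "N", "N", "Y", "?"))
#' @export
build_contingency <- function(status, answers) {
  if (length(status) == 0L) stop_input("empty answer list")
  if (length(status) != length(answers)) {
    stop_input("status and answers must have equal length")
  }
  status <- parse_status(status)
  a <- normalize_answers(answers)
  keep <- a != "?"
  if (!any(keep)) {
    stop_stat("question is untestable: all answers are unknown")
  }
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(status = c("invasive", "non_invasive"),
                                answer = c("yes", "no")))
  tt <- table(status[keep], factor(a[keep], levels = c("Y", "N")))
  tab[, ] <- as.integer(tt)
  list(table = tab, dropped = sum(!keep))
}

#' Two-tailed Fisher exact test p-value
#'
#' Computes the two-sided p-value for a 2x2 table by the
#' point-probability (Fisher–Irwin) rule: with the table margins fixed,
#' sum the hypergeometric probabilities of every table whose probability
#' does not exceed that of the observed table.  The comparison uses a
#' relative slack of 1e-7 to avoid floating-point boundary
#' misclassification — the convention of mainstream implementations.
#'
#' A table with a zero row or column margin carries no information about
#' association; by convention p = 1 is returned with a warning.
#'
#' @param x a 2x2 numeric matrix of counts, or the list returned by
#'   [build_contingency()].
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))  # 2/252
#' @export
fisher_exact <- function(x) {
  if (is.list(x) && !is.null(x$table)) x <- x$table
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L)) || any(x < 0) || any(x != round(x))) {
    stop_input("fisher_exact requires a 2x2 matrix of non-negative counts")
  }
  if (sum(x) == 0) stop_stat("empty contingency table")
  r1 <- sum(x[1L, ]); r2 <- sum(x[2L, ])
  c1 <- sum(x[, 1L]); c2 <- sum(x[, 2L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("zero margin: no association testable, p = 1", call. = FALSE)
    return(1)
  }
  support <- max(0L, c1 - r2):min(c1, r1)
  probs <- dhyper(support, r1, r2, c1)
  d_obs <- probs[match(x[1L, 1L], support)]
  min(1, sum(probs[probs <= d_obs * (1 + 1e-7)]))
}

#' Percent answered per status group
#'
#' The share of species in each status group whose answer to a question
#' is yes or no (as opposed to unknown).
#'
#' @inheritParams build_contingency
#' @return Named numeric vector (exact percentages) with elements
#'   `invasive` and `non_invasive`.
#' @export
pct_answered_by_group <- function(status, answers) {
  status <- parse_status(status)
  a <- normalize_answers(answers)
  vapply(levels(status), function(g) {
    n <- sum(status == g)
    if (n == 0L) stop_stat("empty status group: ", g)
    100 * sum(a[status == g] != "?") / n
  }, numeric(1L))
}

#' Screening criteria for candidate-question reduction
#'
#' A question is eliminated when its two-tailed Fisher exact p-value is
#' not below `alpha` (no statistically significant predictive power) or
#' when it is answered below `min_answered_pct` of the time in *both*
#' status groups (not reliably answerable).  Expert-judgment decisions
#' are expressed declaratively: `overrides` forces retention or
#' elimination of named questions, and `merges` maps candidate question
#' ids onto the id of a merged question.
#'
#' @param alpha significance level (default 0.05).
#' @param min_answered_pct answerability threshold in percent (default 20).
#' @param overrides named character vector, question id to `"retain"` or
#'   `"eliminate"`.
#' @param override_reasons optional named character vector giving the
#'   recorded reason for each override.
#' @param merges named character vector mapping candidate question ids
#'   to the id of the merged question that replaces them.
#' @return A `pre_screening_criteria` list.
#' @export
screening_criteria <- function(alpha = 0.05, min_answered_pct = 20,
                               overrides = character(), override_reasons = character(),
                               merges = character()) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop_input("alpha must be a single value in [0, 1)")
  }
  if (alpha == 0) {
    warning("alpha = 0: every testable question will be eliminated", call. = FALSE)
  }
  if (!is.numeric(min_answered_pct) || min_answered_pct < 0 || min_answered_pct > 100) {
    stop_input("min_answered_pct must lie in [0, 100]")
  }
  overrides <- unlist(overrides) %||% character()
  if (length(overrides) && (is.null(names(overrides)) ||
      !all(overrides %in% c("retain", "eliminate")))) {
    stop_input("overrides must be a named vector of 'retain' / 'eliminate'")
  }
  structure(list(alpha = alpha, min_answered_pct = min_answered_pct,
                 overrides = overrides,
                 override_reasons = unlist(override_reasons) %||% character(),
                 merges = unlist(merges) %||% character()),
            class = "pre_screening_criteria")
}

#' Screen candidate questions against labeled assessments
#'
#' Reproduces the candidate-question reduction pipeline: for every
#' question of `qset`, a 2x2 status-by-answer contingency table is
#' tested with a two-tailed Fisher exact test and the per-group
#' answerability is computed; the question is retained, eliminated or
#' marked merged according to [screening_criteria()].  Every decision
#' records its triggering reason.
#'
#' @param assessments labeled assessment data frame: a `status` column
#'   plus one answer column per question id (see [read_assessments()]).
#' @param qset the candidate [question_set()].
#' @param criteria a [screening_criteria()].
#' @return Data frame with one row per question: `id`, `p_value`,
#'   `pct_answered_invasive`, `pct_answered_noninvasive`, `dropped`,
#'   `decision` (`retain` / `eliminate` / `merged`), `reason`.
#' @export
screen_questions <- function(assessments, qset, criteria = screening_criteria()) {
  qset <- as_question_set(qset)
  if (!inherits(criteria, "pre_screening_criteria")) {
    criteria <- do.call(screening_criteria, as.list(criteria))
  }
  if (!is.data.frame(assessments) || !"status" %in% names(assessments)) {
    stop_input("assessments must contain a 'status' column")
  }
  status <- parse_status(assessments$status)
  if (length(unique(status)) < 2L) {
    stop_stat("both invasive and non-invasive species are required for screening")
  }
  unknown_ids <- setdiff(c(names(criteria$overrides), names(criteria$merges)), qset$id)
  if (length(unknown_ids)) {
    stop_input("override/merge references unknown question id(s): ",
               paste(unknown_ids, collapse = ", "))
  }
  rows <- lapply(qset$id, function(qid) {
    ans <- if (qid %in% names(assessments)) {
      as.character(assessments[[qid]])
    } else {
      rep("?", nrow(assessments))
    }
    pct <- pct_answered_by_group(status, ans)
    p <- tryCatch(fisher_exact(build_contingency(status, ans)),
                  pre_stat_error = function(e) NA_real_)
    dropped <- sum(normalize_answers(ans) == "?")

    low_both <- all(pct < criteria$min_answered_pct)
    if (qid %in% names(criteria$merges)) {
      decision <- "merged"
      reason <- paste0("merged into ", criteria$merges[[qid]])
    } else if (qid %in% names(criteria$overrides)) {
      decision <- criteria$overrides[[qid]]
      reason <- criteria$override_reasons[qid]
      if (is.na(reason)) reason <- paste0("override: forced ", decision)
      else reason <- paste0("override: ", reason)
    } else if (low_both) {
      decision <- "eliminate"
      reason <- sprintf("answerability: answered below %g%% in both groups",
                        criteria$min_answered_pct)
    } else if (is.na(p)) {
      decision <- "eliminate"
      reason <- "untestable: no yes/no answers"
    } else if (p >= criteria$alpha) {
      decision <- "eliminate"
      reason <- sprintf("no predictive power (p = %.4g >= alpha = %g)",
                        p, criteria$alpha)
    } else {
      decision <- "retain"
      reason <- sprintf("p = %.4g < alpha = %g", p, criteria$alpha)
    }
    data.frame(id = qid, p_value = p,
               pct_answered_invasive = pct[["invasive"]],
               pct_answered_noninvasive = pct[["non_invasive"]],
               dropped = dropped, decision = decision, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the instrument that survives screening
#'
#' Materializes a [screen_questions()] outcome as a new question set:
#' retained questions keep their weights, eliminated questions are
#' dropped, and each merge target absorbs its parents with
#' `points_yes` inherited as the maximum over the parents (and the
#' target itself, when it already exists in `qset`) unless an explicit
#' weight is supplied.
#'
#' @param qset the candidate [question_set()] that was screened.
#' @param records the data frame returned by [screen_questions()].
#' @param merge_points optional named numeric vector giving an explicit
#'   `points_yes` for a merge-target id, overriding max-inheritance.
#' @param name,version labels for the resulting instrument.
#' @return A [question_set()].
#' @export
screened_question_set <- function(qset, records, merge_points = numeric(),
                                  name = "screened", version = "1") {
  qset <- as_question_set(qset)
  if (!is.data.frame(records) || !all(c("id", "decision") %in% names(records))) {
    stop_input("records must come from screen_questions()")
  }
  keep <- qset[qset$id %in% records$id[records$decision == "retain"], ]
  merged <- records[records$decision == "merged", , drop = FALSE]
  if (nrow(merged)) {
    targets <- sub("^merged into ", "", merged$reason)
    for (tgt in unique(targets)) {
      parents <- qset[qset$id %in% merged$id[targets == tgt], ]
      pts <- if (tgt %in% names(merge_points)) {
        merge_points[[tgt]]
      } else {
        max(c(parents$points_yes, qset$points_yes[qset$id == tgt],
              keep$points_yes[keep$id == tgt]))
      }
      if (tgt %in% keep$id) {
        keep$points_yes[keep$id == tgt] <- pts
      } else {
        keep <- rbind(keep, data.frame(
          id = tgt,
          text = paste(parents$text, collapse = " "),
          points_yes = pts,
          points_no = max(parents$points_no),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(keep) == 0L) stop_stat("screening retained no questions")
  question_set(keep$id, keep$text, keep$points_yes, keep$points_no,
               name = name, version = version)
}
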