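#' Simulate labeled synthetic assessments
#'
#' Generates a labeled assessment table emulating the answer structure
#' of a screening study: for each species and question, the answer is
#' first unknown with probability `p_missing`, otherwise yes with the
#' species' class-specific probability `p_yes_*` and no with its
#' complement.  Questions are drawn independently (no inter-question
#' correlation structure is imposed); missingness is independent of
#' status unless a per-class value is supplied.
#'
#' Per-question values are given as a single probability recycled over
#' all questions, or a named vector keyed by question id (unnamed ids
#' fall back to the scalar default of 0 for `p_missing`, and must be
#' fully specified for `p_yes_*`).
#'
#' @param qset a [question_set()].
#' @param n_invasive,n_noninvasive positive species counts per class.
#' @param p_yes_invasive,p_yes_noninvasive yes-probability per question
#'   for each class (scalar or named by question id).
#' @param p_missing unknown-answer probability (scalar or named;
#'   default 0).  A list `list(invasive =, non_invasive =)` gives
#'   class-specific missingness.
#' @param seed integer seed; identical seed and configuration give an
#'   identical dataset.  The caller's RNG state is left untouched.
#' @return Data frame in the assessment dialect: `species`, `status`,
#'   plus one `Y`/`N`/`?` column per question id.
#' @examples
#' qs <- pre_questions()
#' sim <- simulate_assessments(qs, 5, 5, 0.9, 0.1, seed = 1)
#' score_assessments(sim, qs, warn_below = 0)
#' @export
simulate_assessments <- function(qset, n_invasive, n_noninvasive,
                                 p_yes_invasive, p_yes_noninvasive,
                                 p_missing = 0, seed = 1L) {
  qset <- as_question_set(qset)
  if (!is.numeric(n_invasive) || !is.numeric(n_noninvasive) ||
      n_invasive < 1 || n_noninvasive < 1) {
    stop_input("species counts must be positive integers")
  }
  py_inv <- expand_prob(p_yes_invasive, qset$id, "p_yes_invasive")
  py_non <- expand_prob(p_yes_noninvasive, qset$id, "p_yes_noninvasive")
  pm <- if (is.list(p_missing)) {
    list(invasive = expand_prob(p_missing$invasive %||% 0, qset$id, "p_missing"),
         non_invasive = expand_prob(p_missing$non_invasive %||% 0, qset$id, "p_missing"))
  } else {
    pm1 <- expand_prob(p_missing, qset$id, "p_missing", default = 0)
    list(invasive = pm1, non_invasive = pm1)
  }

  n_inv <- as.integer(n_invasive); n_non <- as.integer(n_noninvasive)
  with_seed(as.integer(seed), {
    draw_class <- function(n, py, pmiss, prefix) {
      ans <- sapply(seq_along(qset$id), function(j) {
        miss <- runif(n) < pmiss[j]
        yes <- rbinom(n, 1L, py[j]) == 1L
        ifelse(miss, "?", ifelse(yes, "Y", "N"))
      })
      ans <- matrix(ans, nrow = n)
      colnames(ans) <- qset$id
      cbind(data.frame(species = sprintf("%s_%03d", prefix, seq_len(n)),
                       status = prefix, stringsAsFactors = FALSE),
            as.data.frame(ans, stringsAsFactors = FALSE))
    }
    out <- rbind(draw_class(n_inv, py_inv, pm$invasive, "invasive"),
                 draw_class(n_non, py_non, pm$non_invasive, "non_invasive"))
    rownames(out) <- NULL
    out
  })
}

expand_prob <- function(p, ids, what, default = NULL) {
  if (is.null(p)) p <- default
  if (is.null(p)) stop_input(what, " must be supplied")
  p <- unlist(p)
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_input(what, " must contain probabilities in [0, 1]")
  }
  if (is.null(names(p))) {
    if (length(p) == 1L) return(rep(p, length(ids)))
    if (length(p) == length(ids)) return(p)
    stop_input(what, " must be a scalar or named by question id")
  }
  stray <- setdiff(names(p), ids)
  if (length(stray)) {
    stop_input(what, " names unknown question id(s): ",
               paste(stray, collapse = ", "))
  }
  out <- rep(if (is.null(default)) NA_real_ else default, length(ids))
  out[match(names(p), ids)] <- p
  if (anyNA(out)) {
    stop_input(what, " must cover every question id (missing: ",
               paste(ids[is.na(out)], collapse = ", "), ")")
  }
  out
}
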