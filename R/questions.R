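#' Construct a question set
#'
#' A question set is the risk-evaluation instrument itself: an ordered
#' collection of yes/no questions, each worth `points_yes` points for a
#' "yes" answer and `points_no` (0 for all PRE questions) for a "no".
#' Unknown ("?") answers carry no points.
#'
#' @param id character vector of short, unique question identifiers.
#' @param text character vector of question wording.
#' @param points_yes non-negative numeric vector of points awarded for a
#'   yes answer.  Integer for the shipped instrument, but non-integer
#'   custom weights are accepted.
#' @param points_no points awarded for a no answer; must not exceed
#'   `points_yes`.  Defaults to 0.
#' @param name,version labels identifying the instrument.
#' @return A `pre_question_set`: a data frame with columns `id`, `text`,
#'   `points_yes`, `points_no` and attributes `name` and `version`.
#' @examples
#' qs <- question_set(c("a", "b"), c("First?", "Second?"), c(1, 2))
#' max_score(qs)
#' @seealso [pre_questions()] for the shipped 19-question PRE set.
#' @export
question_set <- function(id, text = id, points_yes, points_no = 0,
                         name = "custom", version = "1") {
  id <- as.character(id)
  if (length(id) == 0L) stop_input("a question set must contain at least one question")
  if (anyDuplicated(id)) {
    stop_input("duplicate question ids: ",
               paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  points_yes <- as.numeric(points_yes)
  points_no <- rep_len(as.numeric(points_no), length(id))
  if (any(is.na(points_yes)) || any(is.na(points_no))) {
    stop_input("question point values must be numeric and non-missing")
  }
  if (any(points_no < 0) || any(points_yes < points_no)) {
    stop_input("point values must satisfy points_yes >= points_no >= 0")
  }
  qs <- data.frame(id = id, text = rep_len(as.character(text), length(id)),
                   points_yes = points_yes, points_no = points_no,
                   stringsAsFactors = FALSE)
  structure(qs, name = name, version = version,
            class = c("pre_question_set", "data.frame"))
}

#' The shipped 19-question PRE instrument
#'
#' Returns the PlantRight Plant Risk Evaluation question set with its
#' published point values: 1/0 for sixteen questions, 2/0 for the
#' invasive-elsewhere and climate-match questions, and 3/0 for
#' invasive-elsewhere-in-a-similar-climate, for a maximum attainable
#' score of 23.
#'
#' @return A [question_set()] of 19 questions (`q01` ... `q19`).
#' @examples
#' max_score(pre_questions())
#' @export
pre_questions <- function() {
  path <- system.file("extdata", "pre_question_set.json", package = "pretool",
                      mustWork = TRUE)
  read_question_set(path)
}

#' Read / write a question set as JSON
#'
#' The on-disk form is a JSON object with `name`, `version` and a
#' `questions` array of `{id, text, points_yes, points_no}` records.
#'
#' @param path file path.
#' @param qset a `pre_question_set`.
#' @return `read_question_set()` returns a `pre_question_set`;
#'   `write_question_set()` invisibly returns `path`.
#' @export
read_question_set <- function(path) {
  if (!file.exists(path)) stop_input("question-set file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- obj$questions
  if (is.null(q) || NROW(q) == 0L) {
    stop_input("question-set file has no questions: ", path)
  }
  question_set(q$id, q$text, q$points_yes, q$points_no %||% 0,
               name = obj$name %||% "unnamed",
               version = as.character(obj$version %||% "1"))
}

#' @rdname read_question_set
#' @export
write_question_set <- function(qset, path) {
  qset <- as_question_set(qset)
  obj <- list(name = attr(qset, "name"), version = attr(qset, "version"),
              questions = lapply(seq_len(nrow(qset)), function(i) {
                list(id = qset$id[i], text = qset$text[i],
                     points_yes = qset$points_yes[i],
                     points_no = qset$points_no[i])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Maximum attainable score of a question set
#'
#' The sum of `points_yes` over all questions; 23 for the shipped PRE set.
#'
#' @param qset a `pre_question_set`.
#' @return numeric scalar.
#' @export
max_score <- function(qset) {
  qset <- as_question_set(qset)
  sum(qset$points_yes)
}

as_question_set <- function(qset) {
  if (inherits(qset, "pre_question_set")) return(qset)
  if (is.data.frame(qset) && all(c("id", "points_yes") %in% names(qset))) {
    return(question_set(qset$id, qset$text %||% qset$id, qset$points_yes,
                        if ("points_no" %in% names(qset)) qset$points_no else 0))
  }
  stop_input("not a question set; see ?question_set")
}

#' @export
print.pre_question_set <- function(x, ...) {
  cat(sprintf("Question set '%s' (version %s): %d questions, max score %g\n",
              attr(x, "name"), attr(x, "version"), nrow(x), max_score(x)))
  df <- data.frame(id = x$id, points = sprintf("%g/%g", x$points_yes, x$points_no),
                   text = substr(x$text, 1, 60))
  print.data.frame(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
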