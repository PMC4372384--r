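#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves rounded up (away
#' from zero), the convention used for the instrument's displayed
#' percentages.  Base R's `round()` rounds halves to even, which would
#' print e.g. 92.5 as 92.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(89.47, 9.5, 92.5))
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# classed conditions so the CLI can map failures to exit codes:
# input/format problems -> exit 2, statistical preconditions -> exit 3
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("pre_input_error", "error")))
}

stop_stat <- function(...) {
  stop(errorCondition(paste0(...), class = c("pre_stat_error", "error")))
}

# evaluate code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
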