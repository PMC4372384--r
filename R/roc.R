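#' ROC curve over integer score cutoffs
#'
#' Sweeps every integer cutoff `c` from one below the minimum observed
#' score to the maximum: a species is called positive (high risk) when
#' its score is strictly greater than `c`.  For each cutoff the true
#' positive rate is the fraction of invasive species above the cutoff
#' and the false positive rate the fraction of non-invasive species
#' above it.  Points are deduplicated, sorted, and anchored at (0,0)
#' and (1,1); the area under the curve is the trapezium sum
#' `sum((x[i+1] - x[i]) * (y[i] + y[i+1]) / 2)`, which equals the
#' Mann–Whitney statistic `P(score_inv > score_non) + P(tie)/2`.
#'
#' @param outcomes a [labeled_outcomes()] data frame (integer scores).
#' @return A `pre_roc` list: `points` (data frame `fpr`, `tpr`),
#'   `cutoffs` (data frame `cutoff`, `fpr`, `tpr` before deduplication),
#'   `auroc`.
#' @examples
#' oc <- labeled_outcomes(letters[1:4], c("i", "i", "n", "n"), c(3, 2, 1, 2))
#' roc_curve(oc)$auroc  # 0.875
#' @export
roc_curve <- function(outcomes) {
  outcomes <- as_outcomes(outcomes)
  if (length(unique(outcomes$status)) < 2L) {
    stop_stat("ROC analysis requires both status groups")
  }
  inv <- outcomes$score[outcomes$status == "invasive"]
  non <- outcomes$score[outcomes$status == "non_invasive"]
  cuts <- seq(floor(min(outcomes$score)) - 1L, ceiling(max(outcomes$score)))
  tpr <- vapply(cuts, function(c) mean(inv > c), numeric(1L))
  fpr <- vapply(cuts, function(c) mean(non > c), numeric(1L))
  by_cutoff <- data.frame(cutoff = cuts, fpr = fpr, tpr = tpr)

  pts <- unique(rbind(data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                      data.frame(fpr = fpr, tpr = tpr)))
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, cutoffs = by_cutoff, auroc = auc),
            class = "pre_roc")
}

#' @export
print.pre_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUROC = %.4f\n", nrow(x$points), x$auroc))
  invisible(x)
}

#' @export
plot.pre_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "n", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate (1 - specificity)",
       ylab = "True positive rate (sensitivity)",
       main = sprintf("ROC, AUROC = %.3f", x$auroc), ...)
  abline(0, 1, lty = 3, col = "grey60")
  lines(x$points$fpr, x$points$tpr, type = "b", pch = 19)
  invisible(x)
}

#' Score-frequency histogram by status
#'
#' Counts species per integer score bin per status group — the plot
#' used to place the Accept / Needs-Further-Evaluation / Reject
#' cutoffs by inspecting the separation between the two score
#' distributions.
#'
#' @param outcomes a [labeled_outcomes()] data frame.
#' @param bin_width positive integer bin width (default 1); scores are
#'   binned by `floor(score / bin_width) * bin_width`.
#' @return A `pre_score_histogram` data frame: `bin` (lower edge),
#'   `invasive`, `non_invasive` counts.
#' @export
score_histogram <- function(outcomes, bin_width = 1L) {
  outcomes <- as_outcomes(outcomes)
  if (nrow(outcomes) == 0L) stop_input("no outcomes supplied")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width < 1) {
    stop_input("bin_width must be a positive integer")
  }
  bin <- floor(outcomes$score / bin_width) * bin_width
  bins <- seq(min(bin), max(bin), by = bin_width)
  count_for <- function(st) {
    vapply(bins, function(b) sum(bin == b & outcomes$status == st), integer(1L))
  }
  out <- data.frame(bin = bins, invasive = count_for("invasive"),
                    non_invasive = count_for("non_invasive"))
  class(out) <- c("pre_score_histogram", "data.frame")
  out
}

#' @export
plot.pre_score_histogram <- function(x, ...) {
  m <- t(as.matrix(x[, c("invasive", "non_invasive")]))
  colnames(m) <- x$bin
  barplot(m, beside = TRUE, col = c("firebrick", "steelblue"),
          xlab = "PRE score", ylab = "Number of species", ...)
  legend("topright", legend = c("invasive", "non-invasive"),
         fill = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
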