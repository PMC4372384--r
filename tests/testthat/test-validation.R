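t3_outcomes <- table3_outcomes()

test_that("confusion counts on the published validation set, NFE as error", {
  cn <- confusion_counts(t3_outcomes, "count_as_error")
  expect_equal(cn$TN, 53L)
  expect_equal(cn$FP, 4L)
  expect_equal(cn$TP, 36L)
  expect_equal(cn$FN, 1L)
  expect_equal(cn$IT, 57L)
  expect_equal(cn$NT, 37L)
})

test_that("confusion counts on the published validation set, NFE excluded", {
  cn <- confusion_counts(t3_outcomes, "exclude")
  expect_equal(cn$TN, 53L)
  expect_equal(cn$FP, 0L)
  expect_equal(cn$TP, 36L)
  expect_equal(cn$FN, 0L)
  expect_equal(cn$IT, 53L)
  expect_equal(cn$NT, 36L)
  expect_equal(cn$excluded, 5L)
})

test_that("outright misclassifications are never excludable", {
  oc <- labeled_outcomes(paste0("s", 1:4),
                         c("invasive", "invasive", "non_invasive", "non_invasive"),
                         c(20, 5, 3, 18))
  cn <- confusion_counts(oc, "exclude")
  expect_equal(cn$FP, 1L)  # invasive accepted
  expect_equal(cn$FN, 1L)  # non-invasive rejected
  expect_equal(cn$excluded, 0L)
})

test_that("each species lands in exactly one cell and totals reconcile", {
  set.seed(3)
  for (i in 1:20) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    oc <- labeled_outcomes(
      paste0("s", seq_len(n1 + n2)),
      rep(c("invasive", "non_invasive"), c(n1, n2)),
      sample(0:23, n1 + n2, replace = TRUE))
    for (pol in c("count_as_error", "exclude")) {
      cn <- confusion_counts(oc, pol)
      expect_equal(cn$TN + cn$FP, cn$IT)
      expect_equal(cn$TP + cn$FN, cn$NT)
      expect_equal(cn$IT + cn$NT + cn$excluded, n1 + n2)
    }
  }
})

test_that("inconsistent transcribed classes and one-class inputs error", {
  expect_error(labeled_outcomes("x", "invasive", 20, "Accept"), "inconsistent")
  one_class <- labeled_outcomes(c("a", "b"), c("invasive", "invasive"), c(20, 15))
  expect_error(confusion_counts(one_class), "both invasive and non-invasive")
})

test_that("accuracy metrics reproduce the published percentages", {
  m <- accuracy_metrics(confusion_counts(t3_outcomes, "count_as_error"))
  expect_equal(m$sensitivity, 53 / 57)
  expect_equal(m$specificity, 36 / 37)
  expect_equal(m$overall_accuracy, 89 / 94)
  expect_equal(round_half_up(100 * m$sensitivity), 93)
  expect_equal(round_half_up(100 * m$specificity), 97)
  expect_equal(round_half_up(100 * m$overall_accuracy), 95)

  perfect <- confusion_counts(t3_outcomes, "exclude")
  mp <- accuracy_metrics(perfect)
  expect_equal(unlist(mp), c(sensitivity = 1, specificity = 1, overall_accuracy = 1))
})

test_that("likelihood ratio matches the published value and conventions", {
  cn <- confusion_counts(t3_outcomes, "count_as_error")
  expect_equal(round_half_up(likelihood_ratio(cn), 2), 5.84)
  expect_equal(likelihood_ratio(confusion_counts(t3_outcomes, "exclude")), Inf)
  # no predictive power: equal rejection proportions give LR = 1
  oc <- labeled_outcomes(paste0("s", 1:4),
                         rep(c("invasive", "non_invasive"), each = 2),
                         c(20, 5, 20, 5))
  expect_equal(likelihood_ratio(confusion_counts(oc, "count_as_error")), 1)
  degenerate <- structure(list(TP = 0L, FP = 0L, TN = 1L, FN = 1L,
                               IT = 1L, NT = 1L, excluded = 0L,
                               policy = "count_as_error"),
                          class = "pre_confusion")
  expect_error(likelihood_ratio(degenerate), "undefined")
})

test_that("ROC curve matches hand-derived examples", {
  oc <- labeled_outcomes(letters[1:4], c("i", "i", "n", "n"), c(3, 2, 1, 2))
  roc <- roc_curve(oc)
  expect_equal(roc$auroc, 0.875)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)

  same <- labeled_outcomes(letters[1:6], rep(c("i", "n"), each = 3),
                           rep(c(1, 5, 9), 2))
  expect_equal(roc_curve(same)$auroc, 0.5)
  expect_error(roc_curve(labeled_outcomes("a", "invasive", 5)), "both status")
})

test_that("trapezium AUROC equals the Mann-Whitney statistic", {
  set.seed(19)
  for (i in 1:40) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    inv <- sample(0:23, n1, replace = TRUE)
    non <- sample(0:23, n2, replace = TRUE)
    oc <- labeled_outcomes(paste0("s", seq_len(n1 + n2)),
                           rep(c("invasive", "non_invasive"), c(n1, n2)),
                           c(inv, non))
    auc <- roc_curve(oc)$auroc
    expect_equal(auc, mw_auroc(inv, non), tolerance = 1e-12)
    expect_gte(auc, 0); expect_lte(auc, 1)
    expect_equal(auc == 1, min(inv) > max(non))
  }
})

test_that("ROC points are monotone with anchored endpoints", {
  roc <- roc_curve(t3_outcomes)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_equal(unlist(roc$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), ]), c(fpr = 1, tpr = 1))
})

test_that("score histogram bins per status and validates bin width", {
  h <- score_histogram(t3_outcomes)
  inv_bins <- h$bin[h$invasive > 0]
  non_bins <- h$bin[h$non_invasive > 0]
  expect_equal(range(inv_bins), c(12, 21))
  expect_equal(range(non_bins), c(2, 13))
  expect_equal(sum(h$invasive), 57L)
  expect_equal(sum(h$non_invasive), 37L)

  single <- score_histogram(labeled_outcomes(c("a", "b"), c("i", "n"), c(5, 5)))
  expect_equal(single$invasive + single$non_invasive, 2L)

  two <- labeled_outcomes(c("a", "b"), c("i", "n"), c(2, 3))
  h2 <- score_histogram(two, bin_width = 2)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$invasive + h2$non_invasive, 2L)
  expect_error(score_histogram(two, bin_width = 0), "bin_width")
})
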