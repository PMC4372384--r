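test_that("contingency tables count yes/no per status and drop unknowns", {
  ct <- build_contingency(rep(c("invasive", "non_invasive"), each = 4),
                          c("Y", "Y", "?", "N", "N", "N", "Y", "?"))
  expect_equal(unname(ct$table), matrix(c(2L, 1L, 1L, 2L), 2, byrow = TRUE))
  expect_equal(ct$dropped, 2L)

  all_yes <- build_contingency(c("invasive", "invasive", "non_invasive"),
                               c("Y", "Y", "Y"))
  expect_equal(unname(all_yes$table), matrix(c(2L, 0L, 1L, 0L), 2, byrow = TRUE))

  expect_error(build_contingency(c("invasive", "non_invasive"), c("?", "?")),
               "untestable")
  expect_error(build_contingency(character(), character()), "empty")
})

test_that("two-tailed Fisher p matches hand-enumerated values", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), 2 / 252)
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact(matrix(c(1, 9, 9, 1), 2, byrow = TRUE)), 202 / 184756)
  expect_warning(p <- fisher_exact(matrix(c(3, 0, 2, 0), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p, 1)
})

test_that("Fisher p agrees with the enumeration oracle and fisher.test", {
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)
    expect_equal(p, enum_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant under row/column swap and transposition", {
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(tab[2:1, ]), p)
    expect_equal(fisher_exact(tab[, 2:1]), p)
    expect_equal(fisher_exact(t(tab)), p)
  }
})

test_that("p = 1 for equal-sized groups with identical yes proportions", {
  for (k in 1:5) {
    tab <- matrix(c(k, 10 - k, k, 10 - k), 2, byrow = TRUE)
    expect_equal(fisher_exact(tab), 1)
  }
})

test_that("per-group answerability percentages are computed and rounded", {
  status <- rep(c("invasive", "non_invasive"), c(57, 37))
  answers <- c(rep("Y", 57), rep("Y", 20), rep("?", 17))
  pct <- pct_answered_by_group(status, answers)
  expect_equal(unname(pct["invasive"]), 100)
  expect_equal(round_half_up(unname(pct["non_invasive"])), 54)
  expect_error(pct_answered_by_group(rep("invasive", 3), rep("Y", 3)),
               "empty status group")
})

test_that("screening applies the elimination criteria with recorded reasons", {
  qs <- question_set(c("strong", "null", "sparse", "forced"),
                     points_yes = c(1, 1, 1, 1))
  n <- 30
  df <- data.frame(
    status = rep(c("invasive", "non_invasive"), each = n),
    strong = c(rep("Y", n), rep("N", n)),
    null = rep(c("Y", "N"), n),
    sparse = rep("?", 2 * n),
    forced = rep(c("Y", "N"), n),
    stringsAsFactors = FALSE)
  crit <- screening_criteria(
    overrides = c(forced = "retain"),
    override_reasons = c(forced = "answerable 100% of the time, low p"))
  rec <- screen_questions(df, qs, crit)

  expect_equal(rec$decision, c("retain", "eliminate", "eliminate", "retain"))
  expect_match(rec$reason[rec$id == "null"], "no predictive power")
  expect_match(rec$reason[rec$id == "sparse"], "answerability")
  expect_match(rec$reason[rec$id == "forced"], "override")
  expect_true(rec$p_value[rec$id == "strong"] < 0.05)
})

test_that("answerability elimination requires < 20% in BOTH groups", {
  qs <- question_set("lopsided", points_yes = 1)
  # answered 10% for invasive but 100% for non-invasive: kept testable
  df <- data.frame(
    status = rep(c("invasive", "non_invasive"), each = 20),
    lopsided = c(rep("?", 18), "Y", "Y", rep("N", 20)),
    stringsAsFactors = FALSE)
  rec <- screen_questions(df, qs)
  expect_false(grepl("answerability", rec$reason))
})

test_that("merges and override validation are enforced", {
  qs <- question_set(c("a", "b"), points_yes = c(1, 1))
  df <- data.frame(status = rep(c("invasive", "non_invasive"), each = 5),
                   a = c(rep("Y", 5), rep("N", 5)),
                   b = c(rep("Y", 5), rep("N", 5)))
  rec <- screen_questions(df, qs, screening_criteria(merges = c(b = "a")))
  expect_equal(rec$decision[rec$id == "b"], "merged")
  expect_match(rec$reason[rec$id == "b"], "merged into a")
  expect_error(
    screen_questions(df, qs, screening_criteria(overrides = c(zz = "retain"))),
    "zz")
  expect_error(screen_questions(df[df$status == "invasive", ], qs),
               "both invasive and non-invasive")
})

test_that("the screened instrument inherits merged weights by maximum", {
  qs <- question_set(c("a", "b", "m"), points_yes = c(1, 2, 1))
  n <- 20
  yn <- function() c(rep("Y", n), rep("N", n))
  df <- data.frame(status = rep(c("invasive", "non_invasive"), each = n),
                   a = yn(), b = yn(), m = yn(), stringsAsFactors = FALSE)
  rec <- screen_questions(df, qs, screening_criteria(merges = c(b = "m")))
  out <- screened_question_set(qs, rec)
  expect_equal(sort(out$id), c("a", "m"))
  expect_equal(out$points_yes[out$id == "m"], 2)  # max(parent 2, own 1)

  # explicit weight wins over inheritance; new target ids are created
  rec2 <- screen_questions(df, qs,
                           screening_criteria(merges = c(b = "new", m = "new")))
  out2 <- screened_question_set(qs, rec2, merge_points = c(new = 3))
  expect_true("new" %in% out2$id)
  expect_equal(out2$points_yes[out2$id == "new"], 3)
  expect_equal(max_score(out2), 4)
})
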