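# Independent oracles used across the suite. Deliberately written with
# different arithmetic than the package (choose() products and explicit
# pair enumeration), so agreement is a genuine cross-check.

# Two-sided Fisher p by brute-force enumeration of every 2x2 table with
# the observed margins: sum the probabilities of all tables whose
# probability does not exceed that of the observed table.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  denom <- choose(n, c1)
  p_tab <- function(x) choose(r1, x) * choose(r2, c1 - x) / denom
  p_obs <- p_tab(a)
  total <- 0
  for (x in 0:c1) {
    if (x > r1 || (c1 - x) > r2) next
    px <- p_tab(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  min(1, total)
}

# Mann-Whitney form of the AUROC: P(invasive score > non-invasive score)
# plus half the tie probability, by explicit pair enumeration.
mw_auroc <- function(inv, non) {
  g <- outer(inv, non, ">")
  t <- outer(inv, non, "==")
  (sum(g) + 0.5 * sum(t)) / (length(inv) * length(non))
}

# small three-question instrument with weights 1/2/3 (max score 6)
tiny_qset <- function() {
  question_set(c("a", "b", "c"), c("A?", "B?", "C?"), c(1, 2, 3),
               name = "tiny", version = "t")
}

# random assessment table over a question set, for property tests
random_assessments <- function(qset, n, p_unknown = 0.2) {
  codes <- c("Y", "N", "?")
  probs <- c((1 - p_unknown) / 2, (1 - p_unknown) / 2, p_unknown)
  ans <- replicate(length(qset$id),
                   sample(codes, n, replace = TRUE, prob = probs))
  ans <- matrix(ans, nrow = n, dimnames = list(NULL, qset$id))
  cbind(data.frame(species = paste0("sp_", seq_len(n)),
                   stringsAsFactors = FALSE),
        as.data.frame(ans, stringsAsFactors = FALSE))
}
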