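---
title: "Methods: the PRE instrument, its screening pipeline and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PRE instrument, its screening pipeline and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretool)
```

## The model

The Plant Risk Evaluation (PRE) tool is a weighted additive questionnaire.
A species' assessment is a map from question ids to one of three answer
states — yes, no, unknown — and its score is the sum of per-question
points: `points_yes` for a yes, `points_no` (0 throughout the shipped
instrument) for a no, nothing for an unknown. Unknown is a genuine third
state, not a euphemism for no: it also does not count toward the percent
of questions answered, which is reported alongside the score as an
evidence-level indicator. With the shipped weights (sixteen 1-point
questions, two 2-point, one 3-point) the attainable range is 0–23.

Classification is a step function with an indeterminate middle band:
scores below 11 are **Accept**, above 13 **Reject**, and the closed band
11–13 **Needs Further Evaluation** (NFE), intended for referral to an
expert panel. The cutoffs are configuration
(`classification_rule(accept_below, reject_above)`), not auto-derived:
they were chosen in the source study by inspecting the score-frequency
histogram of known invaders versus known non-invaders
(`score_histogram()` reproduces that view), and the package treats them
the same way — data inform the choice, the rule records it.

Two modelling consequences of "unknown scores zero" are worth stating.
First, scores are monotone in information: answering an unknown question
can only raise (yes) or keep (no) the score, never lower it; the suite
property-tests this. Second, a sparsely answered species is biased toward
Accept. The instrument's authors classified species answered as low as
85 %, so classification is deliberately *not* gated on evidence level;
instead `score_assessments()` warns when percent answered falls below a
configurable threshold (default 80 %) so low-information assessments are
visible rather than silently dropped or blocked.

## Question screening

The 19 shipped questions are the survivors of a 56-question candidate
pool. `screen_questions()` implements the reduction criteria:

1. **Predictive power.** For each question, yes/no answers are
   cross-tabulated against known status (unknowns have no cell and are
   dropped, with the dropped count reported) and tested with a two-tailed
   Fisher exact test; questions with p ≥ α (default α = 0.05) are
   eliminated.
2. **Answerability.** Questions answered less than `min_answered_pct`
   (default 20 %) of the time *in both groups* are eliminated. The
   both-groups reading matters: a question answerable only for invaders
   is still testable and is handled by criterion 1 or by the overrides.
3. **Expert judgment.** Relevance/bias eliminations, forced retentions
   (the source study retained one fragment-propagation question with
   p = 0.2816 on answerability and biological grounds) and question
   merges are declarative configuration (`screening_criteria()`), never
   inferred: the package applies a recorded judgment, it does not invent
   one. A merged question inherits the maximum `points_yes` of its
   parents unless the configuration states otherwise.

Every decision carries its triggering reason in the output record, so a
screening report reads as an audit trail.

The Fisher p-value is computed by the point-probability (Fisher–Irwin)
rule: with margins fixed, sum the hypergeometric probabilities of every
table whose probability does not exceed the observed table's. The
comparison uses a relative slack of 1e-7, matching mainstream
implementations, because an exact `<=` on floating-point hypergeometric
masses misclassifies boundary tables. Degenerate tables with a zero row
or column margin carry no information about association; they return
p = 1 with a warning rather than an error, so a screen over many
questions does not abort on an all-yes question. A question whose
answers are all unknown *is* an error at the contingency level and an
"untestable" elimination at the screening level. α = 0 is accepted (it
eliminates every testable question, with a warning) as a deliberate
"screen nothing through" setting; α ≥ 1 is rejected.

The per-question p-values printed in the packaged `table2` fixture are
transcriptions of the published values: the underlying 35-species 2×2
tables were never published, so those specific p-values are not
recomputable and the package does not pretend otherwise. The fixture's
published column averages (97/97) also do not equal the arithmetic means
of the printed per-question answerability columns (94.7/93.2 by direct
computation); the package computes true means and leaves the printed
bottom row out of the fixture rather than transcribing an unreproducible
aggregate. (The published 97 % figure matches the *per-species* mean
answered fraction in the validation cohort, which is likely what it
reports.)

## Validation statistics

Validation consumes labeled outcomes: species, known status, score,
class. The confusion-cell naming follows the source instrument's
published convention — **TN** is an invader correctly rejected, **TP** a
non-invader correctly accepted — which is the transpose of the usual
epidemiological naming (where the invader would be the "positive").
The package adopts the published convention because it is the one under
which every published number (including LR = 5.84) reproduces, and all
printed reports show both namings side by side to defuse the ambiguity.

The indeterminate NFE band is handled by two policies, both published:

- `count_as_error`: an invader not rejected counts as FP, a non-invader
  not accepted as FN; totals IT/NT are the full class sizes.
- `exclude`: NFE species are removed from counts and totals. Outright
  misclassifications — an invader classified Accept or a non-invader
  classified Reject — are counted as errors under *both* policies; they
  are never excludable, even though the source data happen to contain
  none.

Derived statistics are sensitivity TN/(TN+FP), specificity TP/(TP+FN),
overall accuracy (TP+TN)/(IT+NT), and the base-rate-independent
likelihood ratio LR = (TP/IT)/(FP/NT), which is +Inf when FP = 0 (a
perfect screen; reported as the string `"Inf"` in JSON) and undefined
(an error) when TP = FP = 0.

The ROC curve sweeps every integer cutoff c from one below the minimum
score to the maximum, calling a species positive when its score is
*strictly* greater than c (the published positivity direction: "> 10"
marks the NFE threshold). Points are deduplicated, sorted, anchored at
(0,0) and (1,1), and integrated by the trapezium rule. This construction
provably equals the Mann–Whitney statistic
P(S_inv > S_non) + ½·P(tie), and the suite verifies the identity on
random integer scores. On the packaged validation set the AUROC is
exactly 1 only when the five NFE species are excluded; on the full 94
species it is 2106.5/2109 ≈ 0.9988, strictly below 1 (three score-13
invaders tie the one score-13 non-invader, and the score-12 invader
falls below it). The published headline value of 1 is therefore the
NFE-excluded computation; the package exposes both numbers and does not
guess beyond that.

## Packaged fixtures

The packaged tables transcribe the instrument's published development
data (35-species 56-question cohort), the 19 questions with weights and
screening statistics, and the validation cohort with scores and
classifications, each verified against an MD5 manifest at load time to
guard transcription drift. Two transcription caveats, both resolved in
favour of internal consistency and flagged in the data rather than
hidden:

- The validation table prints 56 invasive and 36 non-invasive rows, but
  its own footnote totals — and every statistic derivable from them —
  count 57 and 37. The fixture therefore carries two placeholder rows
  flagged `source == "synthetic"` (one invasive Reject scored 16, one
  non-invasive Accept scored 6, both strictly inside their class's
  printed score range so no rank statistic is perturbed); filter on
  `source == "printed"` for the rows exactly as published.
- The development cohort's printed minimum invasive total is 20, though
  the accompanying text says 21; the fixture follows the table.

## Synthetic data

`simulate_assessments()` generates labeled assessments from per-class,
per-question Bernoulli yes-probabilities with independent missingness
(optionally status-dependent, since answerability does differ by status
in the real data — one juvenile-period question is answered 89 % of the
time for invaders but 54 % for non-invaders). Questions are simulated
independently because no inter-question correlation structure is
published; real assessments are certainly correlated (invasion history
questions travel together), so simulation-based power results are best
read as upper bounds. The generator is deterministic under a seed and
restores the caller's RNG state; replicates perturb the seed
deterministically from the caller's stream.

Default calibration used by the suite and the acceptance script: 50
species per class, yes-probabilities 0.9 vs 0.1 for a discriminative
question and 0.5 vs 0.5 for a null one, 200 replicates. Under these
conditions the Fisher screen retains the discriminative question in
≥ 99 % of replicates; under the null it eliminates in about 95–99 % of
replicates — above the nominal 95 % floor because the exact test is
conservative on discrete 2×2 margins, which is the expected direction.

## Numerical and display conventions

- Percentages and the likelihood ratio are displayed rounded half-up
  (89.47 → 89, 9.5 → 10), matching the instrument's reporting style;
  base R's half-to-even `round()` is not used for display. All
  machine-readable outputs (CSV, JSON) carry full precision; rounding
  happens only in print methods and in summary quantities whose
  published form is itself rounded.
- Scores are integral with the shipped weights, but non-integer custom
  weights are accepted; the same strict/non-strict inequalities apply,
  so a custom rule owner must place cutoffs accordingly.
- The climate-match question is scored like any other. In the source
  study it provided no separation (all species were already inside the
  evaluation region) yet was retained for future out-of-region use;
  there is no special-casing in the scoring.
- Problem sizes in the test suite: the Fisher implementation is checked
  against a brute-force enumeration oracle exhaustively for all 2×2
  tables with total ≤ 40, the AUROC/Mann–Whitney identity on random
  score sets up to 30 per class, and the screening calibration at
  200 replicates × 100 species; the whole suite and the acceptance
  script each run in well under a minute on one CPU.

## Limitations

The package evaluates *answers*, it does not produce them: answering the
19 questions for a real species requires a literature review that is out
of scope. Confidence intervals for sensitivity/specificity/AUROC are not
computed (none are published to compare against), and predictive values
under realistic base rates (0.1–1 % of introductions become invasive)
are deliberately left to the user: with so low a base rate, even a
high-LR screen will flag mostly false alarms among rejects, which is the
documented trade-off of conservative border screening. The simulator's
independence assumption understates the variance of real score sums.
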