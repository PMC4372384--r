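# pretool — Plant Risk Evaluation (PRE) scoring, screening and validation

`pretool` implements the PlantRight **Plant Risk Evaluation (PRE)** tool, a
weed risk assessment (WRA) instrument designed to screen *ornamental*
plants for invasive potential before they are released to the nursery
trade. It is aimed at horticultural scientists, invasive-plant councils and
nursery certification programs who need a screen that is accurate for
non-invaders as well as invaders, and at methodologists studying
triage-aware screening-test validation.

## The instrument

The PRE tool asks 19 yes/no questions about a species (naturalization
history, invasiveness elsewhere, climate match, competitive impact,
vegetative reproduction, seed biology, dispersal). Each question *i* has a
weight *w<sub>i</sub>*: 1 point for most questions, 2 for "invasive
elsewhere" and "climate match", 3 for "invasive elsewhere in a similar
climate". Unknown answers ("?") carry no points, so the total score is

S = Σᵢ wᵢ · 1[answerᵢ = yes],  0 ≤ S ≤ 23,

reported together with the percent of questions answered. The three-way
outcome is a step function of the score:

- **Accept** (low invasive risk): S < 11
- **Needs Further Evaluation** (NFE): 11 ≤ S ≤ 13
- **Reject** (high invasive risk): S > 13

Around the instrument the package provides:

- **Question screening** — the pipeline that reduced a 56-question
  candidate pool to these 19: per-question two-tailed Fisher exact tests
  (invasive vs non-invasive answer profiles), an answerability filter
  (answered < 20 % of the time in *both* groups), and declarative
  expert overrides/merges (`screen_questions()`).
- **Validation statistics** — confusion counts under two policies for the
  indeterminate NFE band (count-as-error or exclude), sensitivity,
  specificity, overall accuracy, likelihood ratio
  LR = (TP/IT)/(FP/NT), and a ROC curve over integer score cutoffs whose
  trapezium area equals the Mann–Whitney statistic
  P(S_inv > S_non) + ½ P(tie).
- **Synthetic data** — a seeded generator of labeled assessments with
  per-class Bernoulli yes-probabilities and missingness
  (`simulate_assessments()`), so every stage runs with no downloads.
- **Published fixtures** — plain-text transcriptions of the instrument's
  published development and validation tables (`load_fixture()`).
- **A command line** — `exec/pretool` with subcommands `score`,
  `validate`, `roc`, `screen`, `simulate`, `fixtures`.

## Worked example

Score a hypothetical perennial grass that answers yes to eleven 1-point
questions and to nothing else, with the climate question unanswerable:

```r
library(pretool)
qs  <- pre_questions()                       # the shipped 19-question set
ans <- setNames(rep("N", 19), qs$id)
ans[c("q01","q02","q03","q04","q06","q09","q10","q12","q13","q17","q18")] <- "Y"
ans["q05"] <- "?"
score_assessment(ans, species = "Cortaderia selloana (demo)")
#>                      species total_score percent_answered risk_class
#> 1 Cortaderia selloana (demo)          14         94.73684     Reject
```

The score of 14 (q01 = 1, q02 = 2, q03 = 3, plus eight 1-point yeses)
exceeds the reject cutoff of 13, so the species is flagged high risk; 18
of 19 questions (94.7 %) were answerable.

Validating the instrument against the packaged labeled species set, with
NFE outcomes charged as errors:

```r
validation_report(table3_outcomes(), "count_as_error")
#> Confusion counts (policy: count_as_error)
#>   TN (invasive rejected)          53   [std. naming: true positive]
#>   FP (invasive not rejected)       4   [std. naming: false negative]
#>   TP (non-invasive accepted)      36   [std. naming: true negative]
#>   FN (non-invasive not accepted)   1   [std. naming: false positive]
#>   IT 57 invasive, NT 37 non-invasive
#>   Sensitivity (invasive accuracy)     93% (0.9298)
#>   Specificity (non-invasive accuracy) 97% (0.9730)
#>   Overall accuracy                    95% (0.9468)
#>   Likelihood ratio                    5.84
```

53 of 57 known invaders are rejected and 36 of 37 known non-invaders
accepted; the five NFE species are the only "errors". Under the
`"exclude"` policy all accuracies are 100 % and the likelihood ratio is
infinite (no invader is accepted, no non-invader rejected). The report
prints both the instrument's published cell naming and the standard
epidemiological one, because they are swapped relative to each other.

Or from a shell:

```sh
pretool validate --in table3 --out report.json --roc-out roc.csv
pretool simulate --out sim.csv --n-invasive 50 --n-noninvasive 50 \
        --p-yes-invasive 0.9 --p-yes-noninvasive 0.1 --seed 1
pretool screen --in sim.csv --out screening.csv
```

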