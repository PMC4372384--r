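Package: pretool
Title: Plant Risk Evaluation (PRE) Scoring, Question Screening and
    Validation for Ornamental Plants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the PlantRight Plant Risk Evaluation (PRE) tool, a
    weighted 19-question weed risk assessment instrument for screening
    ornamental plants for invasive potential, with a three-way outcome
    (accept, needs further evaluation, reject).  Provides the question
    screening pipeline used to reduce a candidate question pool via
    two-tailed Fisher exact tests and answerability filters, validation
    statistics for screening tests with an indeterminate triage band
    (confusion counts under two policies, sensitivity, specificity,
    overall accuracy, likelihood ratio, ROC curve and trapezium AUROC),
    a seeded synthetic-assessment generator for Bernoulli yes/no answers
    with missingness, packaged transcriptions of the instrument and its
    published validation data, and a command-line interface for batch
    scoring, screening, validation and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
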