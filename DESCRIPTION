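Package: gazeddm
Title: Gaze Dynamics, Confidence and Drift-Diffusion Model Comparison for
    Binary Context-Dependent Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for eye-tracking studies of binary
    context-dependent decisions in which the option images may disappear
    before the choice is reported (look-at-nothing paradigms). Reduces raw
    gaze sample streams to per-interval dwell times and change-of-target
    metrics, fits quartile-binned psychometric curves with a
    shuffle-permutation significance test, relates observation time and
    saccadic alternation to reported cognitive indices through
    per-participant linear models, simulates parallel and sequential
    (gaze-gated) drift-diffusion processes with their closed-form
    confidence readouts, scores three confidence observation models by
    exact conjugate Bayesian linear-model evidence, and compares them with
    random-effects Bayesian model selection (model frequencies and
    exceedance probabilities). A seeded synthetic-data generator emulates
    the full experiment so every stage is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
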