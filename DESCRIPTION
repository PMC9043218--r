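Package: adrtriage
Title: Automatic Causality Assessment and Triage of Adverse Drug
    Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic causality assessment of spontaneous
    adverse drug reaction (ADR) reports.  Fits partial
    proportional-odds cumulative logit models to predict the five-level
    WHO-UMC-style causality category from Boolean report variables,
    computes a per-report warning signal combining assessment
    disagreement and event severity, and supports triage-style
    filtering, evaluation against multinomial-logit and decision-tree
    baselines, and export for parallel-coordinates visualization.
    Includes a synthetic report generator so the whole pipeline is
    testable without access to confidential surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    rpart,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
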