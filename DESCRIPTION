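Package: panelcost
Title: Activity-Based Costing and Budget Impact Analysis for NGS Panel
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for costing next-generation sequencing (NGS) panel tests
    and for estimating the budget impact of changes in molecular diagnostic
    practice. Implements an activity-based costing engine that decomposes
    targeted-gene-panel tests into fixed yearly, fixed per-run and variable
    per-sample components and evaluates cost per patient sample under
    configurable run plans; a deterministic budget impact analysis following
    the ISPOR good-practice framework across time frames and hospital strata
    for stage-IV non-small-cell lung cancer and melanoma populations; one-way
    sensitivity analyses with tornado-ordered output; a before/after
    institutional case-study pipeline with rule-based statistical test
    selection; and a seeded synthetic patient-cohort generator for testing
    the case-study pipeline without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
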