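Package: cicompare
Title: Agreement and Trending Analysis for Paired Cardiac Index Monitor Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Method-comparison statistics for cardiac index monitors measured
    simultaneously and repeatedly within patients. Implements Bland-Altman
    limits of agreement adjusted for repeated measurements via one-way
    variance-components ANOVA, confidence intervals for the bias and both
    limits (MOVER and delta methods), Critchley percentage error with
    cluster-bootstrap intervals, proportional-bias regression with
    patient-clustered standard errors, four-quadrant trending concordance
    with exclusion zones, a four-zone error-grid classification of
    consecutive changes, and equivalence and limits-of-agreement precision
    sample-size calculations. Includes a seeded generator of OPCAB-like
    paired cardiac index cohorts with known ground truth for
    parameter-recovery and coverage testing, and a phase-stratified study
    report mirroring the per-phase table layout of monitor validation
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
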