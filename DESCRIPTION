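Package: markercut
Title: Optimal Cutoff Determination for Continuous and Ordinal Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts a continuous or ordinal biomarker into an optimal
    dichotomization using five families of methods: the density crossing of a
    two-component Gaussian mixture, minimal Fisher p-value against a binary
    outcome, ROC-based optimization (Euclidean distance to the top-left
    corner and Manhattan distance, equivalent to maximizing Youden's J),
    constrained minimum sensitivity or specificity, and minimal log-rank
    p-value against right-censored survival. Produces per-cutoff scans of
    odds ratios, hazard ratios and restricted-mean-survival-time differences
    with confidence intervals, Wilson score intervals for sensitivity and
    specificity, an equivocal-zone recipe for three-way test reporting, and
    the associated overview and at-cutoff diagnostic plots (histogram with
    mixture overlay, OR/HR/survival-difference curves, ROC, waterfall,
    Kaplan-Meier).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    survival,
    ggplot2,
    rlang,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
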