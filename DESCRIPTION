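Package: sterp
Title: Single-Trial ERP Regression with Group-Level Moderation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate analysis of single-trial event-related potential
    (ERP) data across an electrode-by-time grid. Fits per-subject robust
    (iteratively reweighted least squares) regressions of epoched EEG on
    trial-wise task predictors, aggregates the resulting b-value maps to
    group-level one-sample t-maps with Benjamini-Hochberg false discovery
    rate control and peak statistics, and estimates group-level moderated
    brain-brain regressions with Johnson-Neyman regions of significance and
    residualized-trait variants. Includes a synthetic multi-subject cohort
    generator (go/nogo, stop-signal with staircase tracking, incentive
    flanker, and two-step tasks) with known ground truth so that every stage
    of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
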