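Package: coinet
Title: Connection-of-Interest Network Analysis for Pharmaco-fMRI Cross-Over Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis-driven resting-state connectivity analysis for
    two-period cross-over drug trials. Extracts region time series from 4D
    scans by stage-1 dual regression, estimates partial-correlation networks
    with Fisher r-to-z transformation, forms baseline-corrected treatment
    contrasts with per-connection paired t-tests, and tests enrichment of
    significant effects inside a predefined connection-of-interest grid
    (the CLIPST circuitry model of depression) with an exact hypergeometric
    tail. Includes a synthetic-data generator with known ground-truth
    partial-correlation structure for end-to-end validation, and
    noncompartmental pharmacokinetic analysis (Cmax, Tmax, trapezoidal AUC,
    terminal half-life, clearance) of concentration-time profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
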