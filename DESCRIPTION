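Package: mcorrnet
Title: Metabolic Correlation Networks and the Network Growth Rate Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, q-value-thresholded Pearson correlation networks
    from mass-spectrometry metabolomics tables (control-referenced z-scores of
    log2 peak areas), classifies edges as in- or out-of-pathway, extracts
    pathway hub-and-spoke subnetworks with positive-to-negative edge ratios,
    ranks hypercorrelator metabolites between groups, and estimates the
    network growth rate (Vnet), the least-squares slope of significant-edge
    count versus subsample size under ramped random resampling. Includes
    Benjamini-Hochberg and Storey q-value multiple-testing adjustment, a
    latent-factor synthetic cohort generator with analytic ground-truth edge
    structure for calibration and recovery studies, chord-diagram and SIF edge
    exports, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
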