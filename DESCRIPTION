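Package: fetoquant
Title: Absolute Plasma Proteomics Quantification and Marker Panels for
    Diabetic Fetopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free absolute quantification of plasma proteins against a
    spiked dilution-standard (UPS-2-style) calibration ladder, with the
    downstream statistics used in diabetic-fetopathy biomarker studies:
    replicate aggregation and coefficient-of-variation gating of calibration
    points, log-log regression with a prohibited low-amount margin,
    interpolation of normalized total intensities to absolute concentrations,
    NSAF abundance ranking, detection-frequency and group-specific set
    filters, nonparametric five-group comparisons (Kruskal-Wallis,
    Mann-Whitney, Fisher's exact, rank correlations), a generic Fisher
    overrepresentation test with Bonferroni correction, and an integrative
    multi-marker ROC panel with stratified bootstrap confidence intervals and
    leave-one-marker-out elimination. A synthetic-data generator emulates the
    cohort structure and mass-spectrometry intensity model so the whole
    pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
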