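Package: ueff
Title: Ultrasound-Estimated Fat Fraction Calibration and Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates an ultrasound-estimated fat fraction (UEFF) against
    MRI proton density fat fraction (MRI-PDFF) from quantitative ultrasound
    parameters: the attenuation coefficient (AC) and the
    backscatter-distribution coefficient (BSC-D). Provides measurement-level
    quality control and aggregation rules for tissue attenuation, tissue
    scatter distribution, and shear wave elastography readings; exponential
    non-linear least-squares calibration models (single-predictor and
    combined); repeated k-fold cross-validation and frozen-model external
    testing; Pearson correlations with Fisher-z confidence intervals and a
    sub-range correlation scan; Kruskal-Wallis tests with Dunn post hoc
    comparisons and Holm adjustment; ROC analysis with DeLong confidence
    intervals, Youden-index cutoffs, diagnostic metrics and power; and a
    seeded synthetic-cohort generator that emulates the joint structure of
    fatty-liver imaging cohorts so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
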