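Package: cstcnet
Title: Cortico-Striato-Thalamo-Cerebellar Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Static and dynamic resting-state functional-connectivity analysis
    of cortico-striato-thalamo-cerebellar circuits. Provides a synthetic
    BOLD-cohort generator with planted ground truth, fMRI time-series
    preprocessing (initial-volume discard, motion screening, nuisance
    regression, band-pass filtering), winner-take-all parcellation of the
    striatum, thalamus and cerebellum by partial correlation with five
    cortical systems, construction of 20-node connectivity networks
    (Fisher-z partial correlation and sliding-window dynamic-connectivity
    variability), edgewise group statistics with false-discovery-rate
    control, duration-interaction models, F-score ranked linear support
    vector machine classification under nested cross-validation, and
    split-half and window-size reproducibility analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
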