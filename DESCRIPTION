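Package: oculoscreen
Title: Oculomotor Feature Analysis for Free-Viewing Eye-Tracking Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for free visual exploration eye-tracking data
    recorded on a screen-based tracker: gap interpolation, blink removal and
    trial-level quality control; velocity-threshold (I-VT) segmentation into
    fixations and saccades; eleven per-trial oculomotor features in saccadic,
    fixation and scanpath families; duration-weighted scanpath alignment
    dissimilarity with intra- and inter-individual similarity summaries;
    fixed-AOI fixation proportions and intraclass-correlation reliability
    over trial subsets; normality-gated two-group comparisons with effect
    sizes; and subject-level LASSO feature selection with leave-one-out
    cross-validated classification. Includes a synthetic two-cohort gaze
    simulator for power analysis and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    glmnet,
    e1071,
    ranger,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
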