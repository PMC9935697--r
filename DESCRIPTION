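Package: neurovitals
Title: Classifying Level of Consciousness from Routinely Collected ICU
    Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for classifying behavioral level of
    consciousness (coma, vegetative state/unresponsive wakefulness
    syndrome, minimally conscious state minus, command following) in
    neuro-ICU patients from routinely collected physiological signals
    (heart rate, respiratory rate, oxygen saturation and related ICU
    variables). Provides a synthetic cohort generator with realistic
    structured missingness, minute-level resampling with lag-embedded
    k-nearest-neighbour imputation and clinical-range outlier filtering,
    pre-assessment window extraction, wavelet denoising and time-series
    feature extraction, leave-one-patient-out nested cross-validation over
    gradient boosted trees with native missing-value handling, and a full
    evaluation stack: AUROC with DeLong confidence intervals, Youden
    operating points, AUPRC with no-skill baselines, LOWESS probability
    calibration (ICI, Emax) and per-signal relevance scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    xgboost,
    pROC,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
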