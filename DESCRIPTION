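Package: petresponse
Title: Semi-Quantitative FDG-PET Response Prediction for Pediatric Hodgkin Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for early response-to-therapy prediction from paired
    staging/interim FDG-PET scans in pediatric Hodgkin lymphoma. Converts
    calibrated activity volumes to standardized uptake value (SUV) images
    under body-weight, body-surface-area and lean-body-mass (SUL)
    normalizations, segments metabolic tumor volumes (MTV) by fixed and
    individualized liver-background thresholds inside user-defined lesion
    masks, computes SUVmax/SUVmean/MTV/total-lesion-glycolysis and their
    percentage decrease between timepoints, and evaluates each parameter
    as a relapse predictor with DeLong ROC inference, negative-predictive-
    value-constrained cutoff selection, correlated-AUC comparison, false
    discovery rate correction and logistic regression. A seeded synthetic
    PET-cohort generator produces paired phantom scans with known ground
    truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
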