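Package: flourprint
Title: Elemental Fingerprinting and Chemometric Classification of Insect Flours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for discriminating edible insect flours
    (cricket, buffalo worm, mealworm) by their ICP-MS multi-element
    concentration profiles. Provides Eurachem-style method-validation
    arithmetic (calibration fits, limits of detection and quantification,
    spike recovery, relative standard deviation), censored-value handling
    for below-limit trace elements, autoscaled principal component
    exploration with biplots, and two variable-selection-coupled linear
    discriminant classifiers: covariance selection (CovSel) LDA and forward
    stepwise Wilks'-lambda LDA, both with stratified k-fold cross-validated
    subset-size choice and external validation on a held-out test set. A
    synthetic-data generator emulates per-class elemental concentration
    profiles so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
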