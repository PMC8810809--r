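Package: nirglucose
Title: Non-Invasive Glucose Estimation from Multi-Band NIR and Personal
    Medical Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for non-invasive blood glucose
    estimation from multi-band near-infrared (mbNIR) transmittance readings
    combined with personalized medical features (PMF). Provides a
    personalized Beer-Lambert cohort simulator with a scattering-driven
    turning point, a shallow dense neural network (9-50-30-1) glucose
    regressor trained by backpropagation with threshold-based diabetes
    classification and stratified ten-fold cross-validation, and a clinical
    evaluation battery: confusion-matrix metrics, ROC/AUC, Clarke Error
    Grid zoning, Bland-Altman agreement, ISO 15197:2013 accuracy criteria,
    and exclusion-based feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
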