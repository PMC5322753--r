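Package: ildcascade
Title: Two-Stage RBF Network Cascade for Interstitial Lung Disease Risk
    Prediction from Routine Clinical Examination Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts interstitial lung disease (ILD) and pulmonary
    fibrosis risk in rheumatoid arthritis cohorts from routine clinical
    examination indicators (CEIs). Implements ROC analysis with
    Youden-index cutoff selection and the DeLong test, screening of
    ILD-associated indicators, a radial basis function network classifier
    with a 2:1:1 holdout protocol, Euclidean patient-patient similarity
    networks, distance-division derivative features feeding a second-stage
    network, ten-fold cross-validation, external evaluation, and a
    calibrated synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
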