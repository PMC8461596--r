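Package: thermovae
Title: Individual Models of Daily Facial Skin Temperature for Anomaly Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-individual models of normal daily facial skin
    temperature from infrared thermography and flags fever-like anomalies.
    A patch-based convolutional variational autoencoder is trained on 8x8
    patches of min-max normalized facial thermal images spanning the diurnal
    cycle; each test image is reduced to the log-scale mean and variance of
    its patch-wise unregularized anomaly scores, and the resulting 2-D
    statistic is classified by Hotelling theory (squared Mahalanobis
    distance against chi-square back-calculated thresholds). Includes a
    seeded synthetic thermal-protocol simulator, ROC/AUC evaluation, and
    contour visualization of detection probabilities.
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
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
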