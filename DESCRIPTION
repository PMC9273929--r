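Package: plqct
Title: Phantom-Less Quantitative CT Bone Densitometry from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Opportunistic osteoporosis screening from low-dose chest CT.
    Automatically locates the T12 vertebral level, places trabecular,
    paraspinal-muscle and subcutaneous-fat regions of interest, converts
    trabecular Hounsfield units to volumetric bone mineral density (mg/cc)
    by internal two-tissue (fat/muscle) calibration, and classifies
    osteoporosis status against ACR volumetric and WHO DXA T-score criteria.
    Includes a digital chest-CT phantom and cohort simulator with known
    ground truth, and a diagnostic evaluation suite (empirical ROC with
    DeLong confidence intervals and Youden-optimal criteria, confusion
    matrices, age-stratified density trends, RMS-SD/CV precision).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
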