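Package: adnexdss
Title: Decision Support for Ovarian Mass Malignancy Risk from Ultrasound
    Radiomics and Serum CA-125
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to build and evaluate a decision support system that
    predicts the malignancy risk (very low versus medium-high) of ovarian
    masses seen on transvaginal ultrasound. Includes a speckle phantom
    simulator for synthetic cohorts, single-frame DICOM and PNG imaging
    input/output, random contour manipulation for segmentation-robust
    radiomics, IBSI-style morphometric and texture features (grey-level
    co-occurrence, run-length and size-zone families), intraclass-correlation
    feature-stability selection, an ensemble of three echotexture-specific
    classifiers, rule-based integration of acoustic-shadow presence and
    menopause-corrected serum CA-125 thresholds, and diagnostic-accuracy
    metrics with exact Clopper-Pearson binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
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
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
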