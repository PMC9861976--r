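Package: gaquant
Title: Geographic Atrophy Detection and Quantification from SD-OCT Layer
    Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based detection and quantification of geographic atrophy
    (GA) on spectral-domain optical coherence tomography (SD-OCT) macular
    cubes. GA is detected per B-scan as confluence of the ellipsoid zone,
    retinal pigment epithelium and Bruch's membrane segmentation lines,
    dilated into ground-truth masks, compiled into en face GA maps, and
    segmented into discrete lesions that are graded cRORA versus iRORA at
    the 250-micron Classification of Atrophy Meetings (CAM) threshold using
    the anisotropy-corrected greatest linear dimension. Includes a synthetic
    macular-cube phantom generator with hypertransmission contrast, a
    desk-scale encoder-decoder segmentation demonstrator with hard-example
    retraining, patient-grouped data splitting, and a full evaluation suite
    (confusion metrics, Pearson correlation, intraclass correlation with
    confidence intervals, ROC curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
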