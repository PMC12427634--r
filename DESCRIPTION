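Package: cervometry
Title: Automated Distance Measurement on Cervical Spine Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automated analysis of lateral cervical-spine radiographs:
    preprocessing (median denoising, histogram equalization, CLAHE, adaptive
    and Otsu binarization), row-scan localization and cropping of the spine
    region, a pluggable vertebra/neural-foramen detector contract with
    annotation-backed and phantom-oracle backends, reference-point
    localization on each vertebral body, and automated measurement of
    intervertebral and vertebra-to-neural-foramen distances in pixels.
    Includes detection evaluation metrics (precision, recall, average
    precision, mAP) and Pearson agreement analysis between measurement sets,
    plus a synthetic phantom generator with analytic ground truth so the
    whole pipeline is testable without clinical data.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    EBImage,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
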