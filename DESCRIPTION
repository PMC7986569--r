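Package: patchagg
Title: Patch-Cluster Aggregation for Whole-Slide Image Cancer Diagnosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patch-based analysis of whole-slide histopathology images:
    tiling into fixed-size patch grids with two-criterion background
    filtering, patch preprocessing for convolutional classifiers, a
    statistically parameterized simulated patch classifier, slide-level
    diagnosis by topologically connected clusters of positive patches with
    a patient-level union rule, Monte Carlo estimation of the operating
    characteristics linking patch-level error rates to slide- and
    patient-level error, diagnostic evaluation statistics (sensitivity,
    specificity, accuracy, ROC/AUC, Cohen's kappa, paired Wilcoxon
    signed-rank), and per-patch confidence heatmaps aligned to the slide
    raster.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    pROC,
    png,
    tiff,
    yaml,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
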