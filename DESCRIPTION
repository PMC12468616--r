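Package: nengrader
Title: Whole-Slide Grading of Neuroendocrine Neoplasms from Mitotic
    Density Maps and Ki-67 Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for grading neuroendocrine neoplasms (NENs) from
    whole-slide image derivatives. Quantifies the Ki-67 proliferation index
    of immunohistochemistry patches with a classical image-processing chain
    (optical-density colour deconvolution, Otsu thresholding, morphological
    expansion and a circular Hough transform), converts mitotic-figure
    detections into sliding 2 mm^2 density maps with hotspot extraction,
    aggregates slides into clipped histogram-of-density-map feature vectors,
    applies 2019 WHO grading rules and learned histogram classifiers
    (multilayer perceptron and multinomial logistic regression) with naive
    and concatenated stain-combination strategies, and evaluates grade
    stratification with Kaplan-Meier curves, log-rank tests and Harrell's
    concordance index. Seeded synthetic-data generators provide ground-truth
    patches, detection fields and cohorts for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
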