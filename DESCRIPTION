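Package: cxrdebias
Title: Debiasing Pre-Processing and Evolutionary Sample Pruning for Chest Radiograph Nodule Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for homogenizing and debiasing chest radiograph datasets
    before training nodule classifiers: global histogram equalization, lung
    field segmentation with morphological mask repair and quality control,
    close cropping, and a pluggable rib-suppression operator.  Includes an
    evolutionary hard-sample pruning harness that iteratively removes the
    most-misclassified nodule-labelled image under stratified k-fold
    retraining until class balance, an ablation experiment grid over the
    operator toggles, and a synthetic phantom radiograph generator with
    ground-truth lung masks, additive rib and marker layers, per-site
    calibration bias and controllable label noise, so the whole pipeline is
    testable without external image corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    igraph,
    jsonlite,
    withr,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
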