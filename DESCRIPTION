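Package: pollentrace
Title: Producer Classification of Bee Pollen from Macroscopic Color Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the producer (and hence the geographic origin)
    of corbicular bee pollen from macroscopic photographs. Implements
    local-entropy texture segmentation with Otsu thresholding, shadow removal
    by distance to the achromatic axis of the RGB cube, color-space transforms
    to HSV and CIE L*u*v*, color-codebook features learned by mini-batch
    k-means, multiclass classifier selection (polynomial-kernel SVM, random
    forest, multilayer perceptron) by stratified cross-validated weighted F1,
    and evaluation at producer, municipality and sampling-visit level,
    including test-retest reliability between repeated acquisitions. A
    synthetic image generator with known ground truth emulates the structure
    of field-collected pollen image datasets for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jpeg,
    jsonlite,
    nnet,
    png,
    ranger,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
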