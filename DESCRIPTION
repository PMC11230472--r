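Package: torc
Title: Target-Oriented Reference Construction for Supervised Cell-Type
    Identification in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised cell-type identification for single-cell RNA-seq is
    only as good as its reference. This package constructs a reference
    tailored to a given target dataset: a classifier trained on the initial
    reference labels the target, the target's cell-type composition is
    estimated from those predictions, high-confidence target cells (low
    prediction entropy) optionally expand the reference pool, and the pool
    is resampled to match the estimated target composition before the
    classifier is retrained for final labels. Includes a multi-layer
    perceptron classifier behind a pluggable backend contract, F-test
    feature selection, readers for 10X MatrixMarket triplets and dense
    tables, a negative-binomial reference/target simulator with
    controllable composition shift and batch effects, and a benchmarking
    harness comparing reference-construction strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
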