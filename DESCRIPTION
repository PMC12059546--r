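Package: doselevels
Title: Isodose-Level Discretization, Gaussian Smoothing and Plan
    Evaluation for Radiotherapy Dose Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for segmentation-driven radiotherapy dose prediction:
    build the input channels a semantic-segmentation network needs
    (weighted organ-at-risk avoidance image, normalized prescribed dose),
    discretize continuous dose into isodose-level label maps, reconstruct
    continuous dose from predicted levels with a Gaussian smoother, and
    evaluate predicted against reference plans with cumulative isodose
    Dice coefficients, voxel-wise mean absolute percent error,
    dose-volume-histogram metrics with paired Wilcoxon testing, and
    global gamma passing rates computed in compiled code. Includes a
    synthetic prone-breast phantom generator, NIfTI volume input/output,
    and an nnU-Net-style dataset export/import contract so any external
    segmentation backend can be plugged in.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'adapter.R'
    'evaluation.R'
    'smoother.R'
    'phantom.R'
    'grids.R'
    'backend.R'
    'doselevels-package.R'
    'pipeline.R'
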