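Package: instasal
Title: Instance-Level Quantitative Saliency for Volumetric Semantic Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gradient-based pixel attribution for 3D semantic segmentation at
    the level of single object instances (e.g. one white-matter lesion among
    many). Implements SmoothGrad adapted to a lesion domain with mean and
    signed-maximum aggregation, a Grad-CAM++ variant with per-voxel instance
    weights, lesion-instance extraction with connected-component labelling and
    volume filtering, lesion-wise TP/FP/FN/TN example classification with
    control-sphere sampling, peak-value distribution statistics, sanity checks
    with transplanted lesions, and a receptive-field context probe based on
    iterative morphological dilation. Ships small reference segmentation
    models with analytically known derivatives, a trainable tiny CNN, and a
    two-channel phantom generator so the full pipeline runs without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
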