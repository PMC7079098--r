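Package: propnet
Title: Fast Contour Propagation for MR-Guided Radiotherapy with Progressive Registration Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deformable image registration and organ-contour propagation for
    MR-guided adaptive radiotherapy. A progressively trained multi-resolution
    convolutional network predicts a dense deformation vector field from a
    pretreatment/fraction image pair; a spatial transformer layer warps the
    pretreatment clinical target volume mask onto the fraction grid. The
    network is trained entirely on synthetically deformed images with
    segmentation-overlap, deformation-field, or hybrid supervision. Includes
    volume input/output (NIfTI, MetaImage), contour rasterization,
    preprocessing to the network grid, rigid and free-form B-spline
    transforms, a pelvic phantom simulator, and an evaluation suite (Dice,
    95th-percentile Hausdorff distance, centroid distance, Jacobian folding,
    axial-shift robustness, leave-one-out cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
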