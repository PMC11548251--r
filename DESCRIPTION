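Package: piccs
Title: Prior Image Constrained Compressed Sensing Reconstruction for Limited-Data CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative reconstruction of 2D computed-tomography slices from
    sparse-view and limited-angle polychromatic projection data. Implements a
    prior-image constrained compressed sensing solver with a squared-L2
    prior-attachment term, solved by Split Bregman splitting with a matrix-free
    conjugate-gradient inner solver, together with matched fan/parallel-beam
    projectors, filtered backprojection and SART baselines, a polychromatic
    (beam-hardening) projection simulator with counting noise and the standard
    sparse-view/limited-span acquisition schemes, degraded-prior fabrication
    with controllable hallucinations, a compact trainable prior model, and
    PSNR/SSIM/correlation image-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    jsonlite,
    yaml,
    withr,
    rlang,
    tibble,
    generics,
    ggplot2,
    tiff,
    RNifti,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
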