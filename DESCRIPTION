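Package: fusrecon
Title: Freehand 3D Ultrasound Reconstruction by Local Kernel Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs volumetric images from tracked freehand 2D
    ultrasound sweeps. Scattered B-scan pixels are mapped into a world
    frame through per-frame rigid poses, deposited into a voxel grid by
    nearest-voxel bin-filling with mean compounding, and remaining empty
    voxels are filled by Gaussian-weighted local polynomial (kernel)
    regression over a cubic neighbourhood, taking the fitted intercept as
    the voxel estimate. Includes a synthetic phantom and sweep simulator,
    reconstruction-quality metrics, MetaImage volume input/output, and a
    clock-position wall-thickness measurement utility for annular
    structures such as the anal sphincter complex.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
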