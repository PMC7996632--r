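Package: interiorCT
Title: Background-Compensated Interior Tomography for 2D Fan-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 2D fan-beam computed-tomography toolkit for high-resolution
    reconstruction of a region of interest (ROI) from laterally truncated
    projections. A background sinogram, estimated by reprojecting a prior
    low-resolution global reconstruction with the ROI zeroed out, is
    subtracted from the truncated high-resolution local scan, leaving the
    pure ROI sinogram which is reconstructed with filtered backprojection.
    Includes a synthetic head phantom with embedded resolution bar patterns,
    geometric misalignment simulation (isocenter offset, initial view angle,
    magnification error), additive bias correction against a known air
    region, and an image-quality report (SSIM, PSNR, MSE, RMSRE) over
    circular evaluation masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'phantom.R'
    'projector.R'
    'recon.R'
    'compensation.R'
    'metrics.R'
    'io.R'
    'study.R'
    'interiorCT-package.R'
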