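Package: laxm
Title: Limited-Angle Transmission X-ray Microscopy Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for limited-angle
    parallel-beam transmission X-ray microscopy (nano-CT) of cryo-immobilized
    cells. Generates randomized ellipsoid cell phantoms and procedural
    structured images, simulates log-transformed projections over a restricted
    angular window with Poisson counting noise, denoises projections by
    penalized weighted least squares (PWLS), reconstructs slices with Ram-Lak
    filtered back-projection (FBP), and trains a modified residual U-Net
    (zero-padded convolutions, batch normalization, squeeze-and-excitation
    blocks, bilinear upsampling) that predicts and subtracts the missing-wedge
    artifact image from FBP reconstructions. Includes RMSE-in-FOV and SSIM
    evaluation and a training-corpus builder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    jsonlite,
    tools,
    yaml,
    tiff,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
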