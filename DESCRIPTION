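Package: greenCT
Title: Green Learned Post-Processing for Sparse-View CT Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for learned post-processing of
    sparse-view computed tomography. Generates synthetic phantom families,
    simulates parallel- and fan-beam sinograms under full-range and half-range
    (limited-angle) protocols, reconstructs with filtered back-projection, and
    corrects the resulting streak artefacts with two convolutional networks: a
    shallow three-layer single-scale CNN and a residual UNet with additive skip
    connections. Networks are trained with a built-in single-precision
    convolution engine (SGD with Nesterov momentum or Adam, polynomial
    learning-rate decay, gradient clipping). Architectures are compared on
    full-reference image quality (relative error, PSNR, SSIM, FSIM), analytic
    and empirical receptive field, parameter count and FLOPs, including an
    out-of-domain robustness protocol with unseen noise levels and unseen
    image families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
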