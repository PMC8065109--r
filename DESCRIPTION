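Package: vehicle
Title: Variationally Encoded Hi-C Loss Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Resolution enhancement of Hi-C chromatin contact maps with an
    adversarially trained generator conditioned on low-coverage input and
    optimized with a four-part composite objective: adversarial loss,
    variational-autoencoder feature loss, a differentiable insulation-score
    (TAD) loss, and bin-wise mean squared error. Includes contact-map input
    and output with Knight-Ruiz balancing, diagonal-window dataset assembly,
    insulation-score TAD boundary calling, standard evaluation metrics
    (PCC, SPC, MSE, SNR, SSIM), a PCA-parameterized latent-space generative
    explorer, and a synthetic Hi-C generator so the full method runs at desk
    scale. The convolutional networks are implemented in-package on top of
    RcppArmadillo matrix kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
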