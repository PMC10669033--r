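Package: cddpm
Title: Conditional Denoising Diffusion Probabilistic Models for Medical
    Image-to-Image Tasks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Implements conditional denoising diffusion probabilistic models
    (cDDPMs) for paired image-to-image generation in medical imaging:
    the forward Gaussian noising chain and its closed-form marginal, the
    forward posterior, ancestral sampling, the variational lower bound with
    a discretized Gaussian decoder, the simplified epsilon-prediction
    training objective, and a reference conditional U-Net noise predictor
    trained with Adam. Ships task constructors for super-resolution,
    denoising and inpainting conditions, an anatomy-like phantom generator
    so every pipeline runs without external data, and reference image
    quality metrics (accutance, Dice, PSNR).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
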