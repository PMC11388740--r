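Package: irbedpose
Title: In-Bed Human Pose Estimation from Long-Wavelength Infrared Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 2D sleeping-pose estimation of in-bed subjects from
    single-channel long-wavelength infrared (LWIR) frames. Implements
    statistical blanket augmentation based on an exponential attenuation
    model, Gaussian heatmap encoding with a shrinking-radius schedule,
    sub-pixel keypoint decoding via flip-averaged inference and iterative
    centre-of-mass refinement, PCKh evaluation with normalised area under
    the curve, a compact CPU-trainable heatmap pose network, a pose
    discriminator for filtering pseudo-labels during semi-supervised
    domain adaptation from uncovered to covered subjects, and a
    style-transfer GAN for synthesising covered frames. A built-in
    synthetic fixture generator renders articulated 14-keypoint lying
    subjects so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
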