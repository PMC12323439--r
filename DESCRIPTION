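Package: lipseg
Title: Upper-Lip Segmentation with Texture-Augmented Sequential Attention U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised upper-lip segmentation and downstream facial-dysmorphology
    screening. Builds five-channel multidimensional inputs from RGB images using local
    binary pattern (LBP) and gradient-weighted LBP (GLBP) texture descriptors, estimates
    complete closed lip contours from sparse ordered anatomical landmarks via a canonical
    lip template, and trains single and sequential attention U-Nets on the rasterized
    masks. Segmentations are scored with a full metric suite (Dice, IoU, volumetric
    overlap error, Hausdorff distance, pixel accuracy) with paired Wilcoxon comparisons,
    compressed into convolutional-autoencoder latent volumes, and classified (thin-lip
    case versus control) with a 3D convolutional network and a GAN-discriminator
    classifier. Includes a parametric synthetic face/lip generator so the whole pipeline
    is exercisable without restricted clinical data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC
Config/testthat/edition: 3
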