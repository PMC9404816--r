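Package: tangleseg
Title: Multi-Output U-Net Segmentation and Fluorescence Quantification of
    Neurofibrillary Tangles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates a semi-Siamese U-Net -- a single
    convolutional encoder with four parallel decoders -- that segments the
    channel-combination signals (RG, RB, GB, RGB) of three-channel
    immunofluorescence images of neurofibrillary tangles, and quantifies each
    combination as the fraction of segmented pixels.  Includes a synthetic
    fluorescence image generator with consistent four-way ground-truth masks,
    right-angle rotation and elastic-deformation augmentation, deterministic
    k-fold cross-validation with shared initial weights, Dice / IoU /
    true-positive / false-positive evaluation, and a command-line interface.
    The network layers (convolution, max-pooling, nearest upsampling) and the
    Adam optimiser are implemented natively on RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
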