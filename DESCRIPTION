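Package: nodulecascade
Title: Cascaded Convolutional Networks for Pulmonary Nodule Detection in
    Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage cascaded detection of pulmonary nodules in 2D
    chest CT slices: lung-parenchyma segmentation with an inception stem
    and dense skip connections, over-inclusive nodule-candidate detection
    with dilated convolutions, and true-nodule determination with
    multi-resolution convolution blocks and multi-scale pooling. The three
    U-Net-like sub-networks are trained end-to-end with a joint loss
    (pixel-wise MSE, fixed-extractor perceptual loss, and a modified dice
    loss with a negative-sample branch). Includes a seeded synthetic chest
    phantom generator with stage-wise ground truth, lesion- and
    pixel-level evaluation metrics with precision-recall analysis,
    readers and writers for PNG, MetaImage and NIfTI slices, and a
    command-line interface. All network layers, the reverse-mode
    differentiation tape and the convolution kernels are implemented in
    the package (C++ via Rcpp/RcppArmadillo).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
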