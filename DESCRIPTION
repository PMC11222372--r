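Package: dsnet
Title: Dual-Branch 3D Segmentation of Hippocampal Subfields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric segmentation of hippocampal subfields (CA1-3, CA4/DG,
    subiculum) from multi-modal MRI with a dual-branch 3D encoder-decoder
    network. The network combines a convolutional encoder, a multi-head
    self-attention (transformer) bottleneck, convolutional block attention
    (CBAM) on the skip connections, and two decoder branches: one segmenting
    the whole hippocampus, one its subfields, coupled by residual fusion.
    Includes a soft Dice training objective over both branches, Adam training
    with a polynomial learning-rate schedule and patch-based augmentation,
    non-overlapping sliding-window inference with checkpoint averaging,
    connected-component false-positive filtering, Dice and 95th-percentile
    Hausdorff distance evaluation, NIfTI input/output, and a deterministic
    synthetic phantom generator for end-to-end testing without any dataset
    download. All tensor operations, including backpropagation, are
    implemented in the package (Rcpp/Armadillo for the convolutional hot
    paths).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    oro.nifti,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
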