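Package: scseVNet
Title: 3D Brain-Tumor Segmentation with a Squeeze-and-Excitation, Non-Local V-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Volumetric segmentation of multi-modal brain MRI in the BraTS
    style. Implements a V-Net encoder-decoder with residual stages,
    strided-convolution downsampling and transposed-convolution upsampling,
    concurrent spatial and channel squeeze-and-excitation (scSE) gating in
    every stage, and a non-local self-attention block at the bottleneck.
    Includes Z-score intensity normalization, overlapping patch extraction
    and probability stitching, a soft Dice training loss with hand-derived
    gradients and an Adam optimizer, BraTS-style region metrics (Dice,
    sensitivity, specificity, 95th-percentile Hausdorff surface distance),
    and a seeded synthetic phantom generator producing nested ellipsoidal
    tumor cases in NIfTI format so the full train/predict/evaluate pipeline
    runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
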