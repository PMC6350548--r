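Package: mammoseg
Title: Automatic Breast-Tumor Segmentation in Mammograms with an
    ASPP FC-DenseNet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end semantic segmentation of breast masses in digital
    mammograms with a fully convolutional dense network whose bottleneck is
    an atrous-spatial-pyramid-pooling (ASPP) module. Provides declarative
    architecture specification and accounting (layer counts, channel
    bookkeeping, receptive fields), a seedable CPU tensor backend with
    reverse-mode gradients so the networks are trainable at desk scale,
    an inverse-class-frequency weighted cross-entropy loss for the extreme
    foreground/background imbalance of mammograms, Dice/IoU/pixel-accuracy
    evaluation, classical double-threshold baselines, DICOM/PNG/TIFF input
    handling, and a synthetic mammogram-phantom generator with exact
    ground-truth masks for fully reproducible testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: ImageSegmentation, Software
RoxygenNote: 7.3.3
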