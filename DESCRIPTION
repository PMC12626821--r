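Package: melseg
Title: Lightweight Attention Network for Facial Melasma Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements HHBSNet, a lightweight multi-class semantic segmentation
    network for facial melasma (chloasma) images, built from a global
    channel-spatial attention block (per-pixel channel attention, grouped
    channel shuffle, 7x7 spatial attention), a multi-scale cavity fusion block
    (parallel dilated depthwise-separable convolutions at rates 6/12/18 with
    channel and spatial calibration), global feature fusion, and a hybrid
    cross-entropy/focal objective. Includes a pure-R convolution and
    backpropagation engine, SGD-with-momentum training, the full segmentation
    evaluation protocol (mean IoU, accuracy, F1, recall, precision, Dice,
    specificity, confusion matrices, one-vs-rest ROC/AUC, paired t-tests over
    runs), dataset input/output with indexed masks and polygon annotations, and
    a synthetic facial-lesion scene generator for fully reproducible
    experiments without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    rlang,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mgcv,
    optparse,
    yaml
Config/testthat/edition: 3
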