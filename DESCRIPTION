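Package: bonemorph
Title: Automated Murine Bone-Length Measurement from Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for automated morphometry of mouse hind-limb
    bones in dorsal-view radiographs. Provides a synthetic radiograph generator
    with exact ground-truth keypoint annotations, a two-stage keypoint detector
    (convolutional backbone with multi-scale feature fusion, an objectness
    region-of-interest head and a heatmap keypoint head) trained with an
    alternating two-header protocol, keypoint-consistent data augmentation,
    post-processing from detected keypoints to per-bone lengths with outlier and
    abnormal-geometry flagging, and the downstream evaluation statistics
    (objectness accuracy, keypoint mean squared error, manual-versus-automated
    correlation, age- and sex-adjusted residuals, and variance comparison by
    F-test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
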