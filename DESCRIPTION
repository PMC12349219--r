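Package: gazefusion
Title: Gaze-Guided Multimodal Fusion for Radiograph Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for fusing radiologist eye-gaze with chest radiographs
    for multilabel abnormality classification. Renders duration-weighted
    fixation heatmaps from gaze tables, stacks them with the grayscale image
    into a four-channel input, and trains an attention-gated convolutional
    network with a shared backbone and sigmoid multilabel head on a compact,
    fully seeded CPU training engine. Includes Grad-CAM post-hoc explanations
    scored against expert ellipse regions of interest by mean
    intersection-over-union, a striped-noise robustness protocol for fixation
    maps, and a seeded synthetic phantom generator (images, lesions, gaze,
    labels) so the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    pROC,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
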