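Package: drcctnet
Title: Compact Convolutional Transformer Pipeline for Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end tooling for five-grade diabetic retinopathy classification
    from colour fundus photographs at very low resolution. Implements the fundus
    preprocessing chain (Otsu thresholding, region-of-interest cropping,
    morphological opening, non-local means denoising, CLAHE on the luminance
    channel), class rebalancing by random under-sampling with a twelve-transform
    augmentation expansion, a compact convolutional transformer classifier with
    exact trainable-parameter accounting, a seeded synthetic fundus generator for
    desk-scale experiments, training with Adam-family optimizers and decoupled
    weight decay, an image-reduction robustness protocol, and a ten-metric
    confusion-matrix evaluation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
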