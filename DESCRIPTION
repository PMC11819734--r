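Package: equimoco
Title: Momentum-Contrast Representation Learning for Equine Posture Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for unsupervised analysis of horse
    posture imagery: video frame sampling and crop retrieval with
    resolution and intensity-variability quality filters, asymmetric
    edge-emphasising (Sobel) query/key augmentations, a lightweight
    single-channel convolutional encoder pretrained with momentum
    contrast and a normalized temperature-scaled cross-entropy
    (NT-Xent/InfoNCE) objective, a frozen-encoder downstream emotion
    classifier, and t-SNE embedding-space cluster analysis.  Includes a
    synthetic posture-silhouette fixture generator so the whole pipeline
    is testable without proprietary footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    ggplot2,
    jsonlite,
    png,
    Rtsne,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
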