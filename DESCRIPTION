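Package: wcepipe
Title: Saliency-Guided Segmentation and Optimized Deep Features for
    Gastrointestinal Endoscopy Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for wireless capsule endoscopy
    (WCE) style RGB frames: hybrid morphological/dehazing contrast enhancement,
    saliency-map lesion segmentation driven by a compact 14-layer convolutional
    network, backbone feature extraction (MobileNetV2-topology or a tiny test
    network) with Gaussian-process Bayesian optimization of fine-tuning
    hyperparameters, hybrid Whale/Harris-Hawks wrapper feature selection with an
    extreme-learning-machine fitness, and ELM classification with standard
    evaluation metrics. Includes seeded generators for endoscopy-like synthetic
    frames with ground-truth lesion masks and for feature tables with planted
    informative dimensions, so the whole chain is testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
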