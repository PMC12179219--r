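Package: ivcmad
Title: Unsupervised Anomaly Detection for Corneal In Vivo Confocal Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature-reconstruction anomaly detection for corneal in vivo
    confocal microscopy (IVCM) images. A frozen convolutional backbone yields a
    multi-scale feature pyramid that a trainable fusion network merges into a
    token grid; a transformer with neighbor-masked encoder attention and
    layer-wise query decoders, trained on normal images only, reconstructs the
    grid. Per-token reconstruction error gives calibrated 0-255 anomaly scores,
    blue-to-red explainability heatmaps, and ROC-based evaluation statistics
    (DeLong confidence intervals and paired tests, Youden-optimal thresholds,
    confusion metrics, exact Mann-Whitney rank tests). A seeded synthetic
    generator emulating the four normal corneal layer textures (epithelial
    mosaic, sub-basal nerve plexus, stromal keratocytes, endothelial mosaic)
    with injected lesions makes the whole pipeline testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
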