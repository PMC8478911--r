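Package: reefquad
Title: Photoquadrat Processing and Benthic Cover Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for reef photoquadrat monitoring pipelines: synthetic
    quadrat scene and cover-series generation with known ground truth,
    PVC-frame detection with rotation rectification and inside-edge cropping,
    red-channel color balancing for green/blue underwater casts,
    confidence-gated point annotation with CoralNet-style CSV interchange,
    percent-cover estimation with resampling medians and image-area bias
    checks, beta-distribution generalized additive models for temporal cover
    trends, and community ordination (NMDS and redundancy analysis with
    permutation ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    vegan,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
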