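Package: trapslim
Title: Lightweight Camera-Trap Wildlife Recognition Models that Resist
    Shortcut Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing compact convolutional wildlife
    recognition models from camera-trap imagery while mitigating shortcut
    learning, the tendency of classifiers to key on per-site background
    signatures instead of the animal. Provides mixed data augmentation
    (copy-paste image synthesis plus regional background suppression
    outside the animal's bounding box), genetic-algorithm channel pruning
    with adaptive batch-normalization recalibration, knowledge-distillation
    fine-tuning of the pruned student, Grad-CAM based foreground-attention
    metrics (FRoH), exact parameter and multiply-accumulate accounting from
    architecture descriptors, and a synthetic camera-trap scene generator
    with a controllable wildlife-background confound for desk-scale
    benchmarking of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
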