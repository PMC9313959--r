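Package: cpgnet
Title: Channel Pruning and Ghost Decomposition for Convolutional Image
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for structured compression of bottleneck residual
    convolutional classifiers.  Channels are ranked by the magnitude of
    their batch-normalization scale factors and pruned per layer at
    controllable rates, and the surviving convolutions can be decomposed
    into a primary convolution plus cheap depthwise linear operations
    (ghost modules).  Includes exact parameter, FLOP and multiply-add
    accounting with per-layer reports, a pure-R training and evaluation
    engine for desk-scale experiments, a seeded synthetic two-class
    chest-image generator, and a command-line interface for the full
    compress/report/train/evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
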