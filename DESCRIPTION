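Package: v2texture
Title: Texture Sensitivity of Convolutional Feature Hierarchies Compared
    to Early Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the sensitivity of layered convolutional
    feature models to higher-order texture statistics, mirroring the analysis
    used to characterise neurons in primate visual areas V1 and V2. Provides
    paired naturalistic/spectrally-matched-noise stimulus preparation via
    Fourier phase randomization, a configurable convolution-rectification-
    pooling-normalization feature extractor with receptive-field arithmetic,
    per-neuron modulation-index computation, three population fitting
    procedures (greedy forward subset selection, simplex-constrained least
    squares over the full population, and a ridge-regularized subset
    variant), and leave-one-group-out / leave-family-out cross-validation.
    A synthetic-data module generates texture-like image families and
    model-neuron response tensors with planted structure so the whole
    pipeline is testable without external stimulus sets or pretrained
    weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    jsonlite,
    png,
    yaml,
    ggplot2,
    rlang,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    e1071,
    tiff,
    withr
Config/testthat/edition: 3
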