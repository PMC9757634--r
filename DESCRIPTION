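Package: TwinVAE
Title: Semi-Supervised Twin Variational Autoencoders for Suspension-Cell
    Counting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Counts suspension cells (for example CHO-K1 grown in
    microfluidic cultivation chambers) in grayscale microscopy images with
    a Siamese pair of convolutional variational autoencoders that share
    their innermost encoder, bottleneck and first decoder stage.  One twin
    handles natural micrographs, the other synthetic renderings with exact
    ground-truth counts, and a shared regression head predicts the cell
    count from the common latent representation.  Includes a seeded
    generator of synthetic suspension-cell images in two visual styles
    (bright-field-like and phase-contrast-like), the composite twin loss
    with per-modality weights, semi-supervised training with the matching
    augmentation stack, four layer-freezing transfer-learning schemes with
    a synthetic:natural batch-ratio sampler, and evaluation utilities
    (count-error metrics, cross-decoder reconstruction checks and seeded
    UMAP latent-space projections).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    png,
    EBImage,
    jsonlite,
    yaml,
    uwot
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'TwinVAE-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'constructors.R'
    'model.R'
    'checkpoint.R'
    'io.R'
    'evaluation.R'
    'training.R'
    'transfer.R'
    'cli.R'
    'synthgen.R'
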