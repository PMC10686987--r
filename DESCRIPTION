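Package: skullmil
Title: Gated Attention Multiple-Instance Learning for Skull-Based Sex Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex estimation from binarized three-dimensional skull volumes with
    gated attention-based multiple-instance learning. A whole skull volume is
    tiled into a grid of patches (the "bag"), each patch is embedded by a small
    3D convolutional encoder, and a gated attention mechanism pools the patch
    embeddings into a single bag representation that is classified as female or
    male. The package covers the full analysis pipeline: NIfTI volume
    preprocessing (isotropic resampling, canonical reorientation, crop/pad,
    Hounsfield-unit binarization), age balancing of the two sexes by 1:1
    propensity-score matching with a caliper, 3D training-time augmentation
    including cutout and partial-affine operators that emulate injured skulls,
    network training with early stopping, evaluation metrics with
    difference-of-proportion confidence intervals, and attention-weighted
    volume heatmaps for interpretation. A seeded synthetic skull-volume
    generator provides class-labelled data with a sex-dependent mandible shape
    signal so the whole pipeline is testable without access to any CT archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
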