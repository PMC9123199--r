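Package: epigan
Title: Conditional-GAN Bias-Field Correction and Brain Extraction for 3D EPI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects receive-coil intensity inhomogeneity and extracts the
    brain from 3D echo-planar imaging (EPI) volumes in a single pass with a
    volumetric pix2pix conditional GAN (a six-layer 3D U-Net generator and a
    3D PatchGAN discriminator trained with an adversarial plus L1 objective).
    Includes a synthetic rodent-head phantom generator with a single-loop
    surface-coil sensitivity model for paired training data, a full training
    engine with per-epoch checkpointing and MSSIM-based checkpoint selection,
    a learning-rate grid-search helper, and the volumetric similarity suite
    (cosine angle distance, L2 norm, MSE, PSNR, windowed MSSIM, Dice) used to
    evaluate predictions. Volumes are read and written as NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
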