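Package: ReceptorGAN
Title: Conditional GAN Translation of Cell-Body Stained Cortex into
    Receptor Autoradiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cross-modality image translation for cortical brain sections:
    predicts neurotransmitter-receptor autoradiography patches (M2, kainate)
    from high-resolution cell-body stained image patches of macaque areas V1
    and M1 with conditional generative adversarial networks. Provides the
    full pipeline around the models: a synthetic paired-section simulator
    with known laminar density profiles and deformations, dense deformation
    field application/inversion and landmark validation, cortical midline
    spline fitting and overlapping 2 mm patch-pair extraction across a 16x
    resolution gap, three cGAN conditioning variants with batch-instance
    normalization trained with an adversarial plus L1 objective, image
    quality metrics (z-score MAE, PSNR, SSIM, FID) with worst-case
    aggregation, and patch inpainting with min-max contrast enhancement for
    section-level reconstruction. Convolutional layers and backpropagation
    are implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'ReceptorGAN-package.R'
    'alignment.R'
    'nn_core.R'
    'cgan_models.R'
    'io.R'
    'reconstruction.R'
    'evaluation.R'
    'training.R'
    'patch_sampling.R'
    'synthetic_cortex.R'
    'cli.R'
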