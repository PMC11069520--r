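Package: octsynth
Title: Generative Choroidal Enhancement for Paired Optical Coherence
    Tomography Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for cross-device optical
    coherence tomography (OCT) choroidal enhancement. Generates seeded
    synthetic paired shallow-penetration (SDOCT-like) and deep-penetration
    (SSOCT-like) retinal OCT volumes with known layer geometry, harmonizes
    and co-registers the pairs (Lanczos resampling, anisotropic-diffusion
    despeckling, RPE flattening, enface phase-correlation registration),
    trains a paired conditional-GAN image translator (ResNet-9 generator,
    70x70 PatchGAN discriminator) that restores choroidal visibility, and
    quantifies retinal and choroidal metrics (subfoveal thickness, area,
    volume, and the Niblack-thresholded choroidal vascularity index)
    together with agreement statistics (Pearson r, ICC(2,1), MAE with
    bootstrap confidence intervals, Bland-Altman limits of agreement, and
    reader-study scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils-image.R'
    'phantom.R'
    'preprocess.R'
    'nn.R'
    'translate.R'
    'metrics.R'
    'agreement.R'
    'io.R'
    'pipeline.R'
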