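Package: recoilr
Title: Laser-Ablation Recoil Analysis and Epithelial Tension Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cortical tension and Myosin distribution in epithelia
    from laser-ablation experiments and fluorescence microscopy. Fits the
    Kelvin-Voigt viscoelastic recoil model L(t) = D*(1 - exp(-t/tau)) to
    vertex-track time series to estimate the recoil amplitude D and the
    relaxation time tau (the viscosity-to-elasticity ratio), computes initial
    retraction velocities, extracts fluorescence linescans from image stacks
    and summarises them by mean intensity and heterogeneity (sd/mean),
    quantifies mosaic-clone morphometry as clone-to-control ratios, and
    compares conditions with Mann-Whitney, Student's t and one-way ANOVA
    tests. A synthetic-data generator produces recoil trajectories,
    epithelium images and clone measurement ensembles with known ground
    truth so every stage of the pipeline can be validated.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
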