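Package: mullins
Title: Rule-of-Mixtures Constitutive Models for Stress Softening and
    Residual Strains in Soft Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hyperelastic constitutive modelling of biological tissues and
    biocompatible materials under uniaxial extension and compression. The
    total strain energy is split by the rule of mixtures into an amended
    non-Gaussian (eight-chain, inverse-Langevin) isotropic matrix part and an
    isotropized eight-chain fiber part. Stress softening (Mullins effect) and
    permanent set are modelled by a non-monotonous exponential softening
    kernel with a residual-strain energy term, and alternatively by a
    modified Dorfmann-Ogden pseudo-elastic unloading law. Includes a
    loading-unloading cycle simulator with deformation-history tracking,
    bounded Levenberg-Marquardt parameter calibration to stress-stretch
    curves, packaged literature parameter sets for vaginal tissue, mouse
    skin, suture materials, human trachea and brain tissue, and a seeded
    synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
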