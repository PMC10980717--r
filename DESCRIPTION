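Package: supercoilr
Title: Analysis of Single-Molecule DNA Supercoiling Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of correlative optical/magnetic
    tweezers experiments on torsionally constrained DNA: trap and angular
    calibration from position power spectra and driven-rotor phase lags,
    worm-like-chain force-extension fitting with bootstrap errors,
    supercoiling density and torque arithmetic, hat-curve assembly with
    drift correction and buckling detection, fluorescent puncta (plectoneme)
    tracking with base-pair content and diffusion estimation, sequence-based
    prediction of denaturation-bubble and plectoneme sites, base-pair-parameter
    trajectory analysis for denaturation bubbles, restraint-specification
    generation for tension/torsion-controlled duplex simulations, and a
    steady-state heat-conduction model for a laser-heated magnetic bead.
    Includes seeded synthetic-data generators for every input so each
    estimator can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    Matrix,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
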