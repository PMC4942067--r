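Package: mitovolt
Title: Absolute Millivolt Calibration of Mitochondrial and Plasma
    Membrane Potentials from Potentiometric Dye Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring the absolute magnitude and time course of
    the mitochondrial membrane potential and the plasma membrane potential
    in intact cells from dual-probe fluorescence time-lapse recordings
    (non-quench mode TMRM plus an anionic bis-oxonol plasma membrane
    potential indicator). Implements a three-compartment probe
    redistribution model with Goldman-Hodgkin-Katz plasma membrane flux, a
    forward fluorescence simulator, the inverse millivolt calibration with
    per-cell regressions, delta-method error propagation and quality
    control, confocal stereology estimators for the mitochondria:cell
    volume fraction and the apparent activity coefficient ratio,
    post-calibration heterogeneity and sensitivity analyses, a quench-mode
    rhodamine 123 artifact simulator, and a synthetic data generator that
    produces protocol traces and two-channel image fields with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
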