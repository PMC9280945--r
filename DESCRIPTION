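Package: svquench
Title: Stern-Volmer Analysis of Fluorescence Quenching Titrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing steady-state and time-resolved fluorescence
    quenching experiments in the Stern-Volmer framework. Fits the modified
    Stern-Volmer (quenched-fraction) model to intensity-vs-quencher
    titrations, evaluates the sphere-of-action static quenching volume and
    kinetic distance, extrapolates the zero-concentration Stern-Volmer
    constant under the finite-sink approximation to obtain diffusion
    coefficients, distance parameters and encounter rates, classifies the
    quenching mechanism (static vs dynamic, diffusion-limited or not), and
    fits multiexponential TCSPC decay histograms. Includes seeded synthetic
    generators for titrations and photon-counting decays so every estimator
    can be exercised in parameter-recovery experiments, plus CSV/JSON
    readers and writers for titration tables, spectra, decays and analysis
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
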