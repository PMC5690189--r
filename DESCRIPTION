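Package: dvhrisk
Title: Late-Toxicity Risk Modelling from Radiotherapy Dose-Volume Histograms
Version: 0.1.0
Authors@R:
    person("dvhrisk", "maintainers", email = "dvhrisk@example.org", role = c("aut", "cre"))
Description: Tools to estimate late radiation toxicity from organ-at-risk
    dose-volume histograms (DVHs) in thoracic radiotherapy, aimed at modality
    comparison studies for Hodgkin lymphoma. Implements the relative seriality
    model (Poisson statistics) for excess risk of cardiac mortality, and the
    Schneider modified linear-quadratic / organ-equivalent-dose model for
    excess absolute risk of radiation-induced lung and breast cancer. Includes
    a DVH data model with CSV input/output, differential/cumulative
    conversions, rebinning and dose-volume metrics; a seeded generator of
    modality-characteristic synthetic DVH cohorts (3D conformal photons,
    helical tomotherapy, intensity-modulated proton therapy); cohort-level
    comparison via per-patient risk tables, modality risk ratios and paired
    t-tests; and sensitivity analyses for absolute dose uncertainty and a
    uniform secondary-neutron dose bath.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
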