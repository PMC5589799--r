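Package: morphonorm
Title: Single-Subject Normative Modelling of Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds normative models of regional brain morphometry (volumes and
    surface-based measures over the Desikan-Killiany and Destrieux parcellations)
    from a control cohort with polynomial age trends, repeated-scan measurement
    error and per-feature artifact odds; scores single patient scans for regional
    abnormalities with two-sided p-values, false-discovery-rate flags, signed
    log-p abnormality fingerprints and odds-weighted regional detection scores;
    selects subtype-representative features by reproducibility and uniqueness
    heuristics; and evaluates detections against expert, surgical and EEG ground
    truth with diagnostic odds ratios, predictive values and randomization
    statistics. Includes a synthetic-data generator emulating the full
    2,976-feature schema for testing and calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
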