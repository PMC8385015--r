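Package: chipPKPD
Title: PK-Mimicking Dosing Schedules and Spheroid Response Quantification
    for Tumour-on-Chip Platforms
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for running pharmacokinetically faithful drug exposure
    experiments on perfused tumour-spheroid ("tumour-on-chip") platforms.
    Simulates and fits one-compartment free-plasma pharmacokinetic (PK)
    profiles, discretises a continuous PK curve into a timed multi-reservoir
    stepwise exposure schedule (equal-AUC partition by default), composes
    multi-day mono- and combination-treatment timelines including gapped
    schedules, plans the two-step dilution from DMSO stocks to per-reservoir
    working concentrations, simulates schedule-dependent spheroid growth
    inhibition with a damage-gated pharmacodynamic model, and quantifies
    spheroid response from multichannel images (Feret-diameter volumetry,
    area-normalised biomarker-positive cell counts) with a matched synthetic
    image generator providing ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
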