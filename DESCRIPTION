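Package: ivtsim
Title: Mechanistic Simulation and Optimization of Fed-Batch In Vitro
    Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modeling of fed-batch in vitro transcription (IVT)
    for RNA synthesis. Couples differential equations for T7 RNA polymerase
    kinetics with instantaneous ionic speciation equilibria to predict pH,
    effective salt concentration, magnesium phosphate supersaturation, RNA
    yield, and co-transcriptional cap fraction along batch and fed-batch
    trajectories. Includes feed-policy optimization by setpoint-tracking
    objectives, D-optimal design of capping calibration experiments,
    maximum-likelihood estimation of capping parameters with Monte Carlo
    prediction intervals, and generators for synthetic reference scenarios
    and measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    tools,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    lhs,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
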