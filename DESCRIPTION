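Package: fluidloop
Title: Simulated Syringe-Pump Fluidics and Event-Driven Microscopy Orchestration
Version: 0.1.0
Authors@R:
    person("fluidloop", "developers", email = "fluidloop@example.org",
           role = c("aut", "cre"))
Description: A hardware-agnostic reimplementation of an open-source
    microscope fluid-exchange automation stack. Provides syringe-pump
    kinematics (volume/step/flow-rate conversions and a physically
    plausible dispense-error simulator), a simulated multiplexed pump
    bus of up to 128 addressable units plus a peristaltic extraction
    pump, a declarative fluid-exchange protocol engine with chamber
    bookkeeping and execution logging, a dispense calibration and
    quality-control analysis (accuracy/precision as percent of nominal),
    an unsupervised mitotic-rounding detector (Otsu segmentation,
    morphological opening, circularity 4*pi*A/P^2 with a sub-pixel
    contour perimeter), a synthetic time-lapse generator of rounding
    cells, and an acquisition orchestrator that closes the loop from
    live imaging through event detection to in-situ fixation/staining
    and post-fixation imaging. Everything runs against a simulated
    clock so experiments are testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
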