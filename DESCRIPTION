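Package: flowLadder
Title: Ladder-Pulse Analysis for Constrictional-Microchannel Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@flowladder.org",
           role = c("aut", "cre"))
Description: Detects and fits ladder-shaped (trapezoidal) fluorescence pulses
    in multi-channel photomultiplier traces recorded while single cells
    transit a constrictional microchannel, converts plateau intensities into
    absolute per-cell protein copy numbers through a volume-equivalence
    calibration against gradient dilution series, inverts pulse timing into
    cell velocity and diameter, and classifies cell types with a feedforward
    network on quantified protein features or a recurrent (LSTM) network on
    the raw pulse shapes. A seeded synthetic-trace generator emulates the
    instrument so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
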