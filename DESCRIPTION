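Package: placeframes
Title: Dual-Frame Analysis of Active Place Avoidance and Place-Cell Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rodent behaviour and hippocampal single-unit
    recordings on a rotating arena in which a stationary (room-frame) shock
    sector dissociates two spatial frames. Provides coordinate transforms
    between the room and arena frames, behavioural end-point measures
    (path length, shock-zone entrances, time to first entry, savings index),
    single-unit discharge metrics and cell-type gates, episode-level
    overdispersion of place-cell firing against an inhomogeneous-Poisson
    expectation, spatial-frame-specific momentary positional information
    (Ipos), ensemble spatial-frame preference (SFEP) with runs-test
    significance and spatial preference maps, and interregional
    cytochrome-oxidase covariance networks with FDR-tiered edges. A
    synthetic-session generator (Ornstein-Uhlenbeck foraging, frame-locked
    Gaussian place fields, latent frame switching, per-pass gain modulation)
    makes every stage testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
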