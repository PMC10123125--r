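Package: bowkit
Title: DNA Bow Assay Analysis: Oligonucleotide Hybridization Kinetics Under Weak Tension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for DNA bow experiments, in which a bent
    double-stranded DNA arc exerts piconewton-scale tension on a
    single-stranded DNA target monitored by single-molecule FRET. Provides
    worm-like-chain end-to-end distance distributions and force-extension
    relations for tension calibration, rigid-base-pair energy minimization
    for intrinsically curved arcs, two-state dwell-time and rate extraction
    from FRET intensity trajectories, force-dependent rate laws and their
    closed-form linear force-extension approximations with joint model
    fitting, nearest-neighbor duplex thermodynamics, umbrella-sampling
    reweighting of two-dimensional melting free-energy landscapes, and
    seeded synthetic-data generators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
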