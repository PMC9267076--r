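Package: bistaloop
Title: Bistable Double-Inhibitory Loop Models of Amyloid-Beta/Prion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing planar double-inhibitory
    (double-negative) feedback loop models with decreasing Hill-type
    inhibition, as used to describe the mutual inhibition between the
    cellular prion protein (PrPC) and the BACE1/amyloid-beta axis in
    Alzheimer's disease pathogenesis. Provides ODE simulation, exhaustive
    equilibrium location via a monotone one-dimensional reduction,
    linear stability classification, bifurcation diagrams over a
    cyclic-nucleotide (cAMP/cGMP) stimulus with saddle-node (fold)
    detection, quasi-static hysteresis protocols, basin-of-attraction
    maps with separatrix estimation, a seeded model sampler for testing,
    and a command-line interface with CSV/JSON interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
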