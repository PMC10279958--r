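Package: spnsim
Title: Simulation and Robustness Analysis of the Drosophila Segment
    Polarity Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and analysis of the segment polarity gene
    network of the Drosophila embryo as a multicellular reaction model on
    a periodic hexagonal cell lattice.  Provides numerically guarded
    Hill-type rate laws that remain finite under integrator overshoot,
    stiff time-course integration (LSODA) through a compiled
    right-hand side, random-parameter robustness screening with a
    stripe-pattern score, a steady-state multistability census by
    integration from random initial conditions, and SBML Level 3
    Version 1 export/import so the model can be exchanged with other
    simulators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
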