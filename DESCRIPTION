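Package: bivalentSim
Title: Stochastic Lattice Simulation of Bivalent Histone Modification Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discrete-time stochastic simulation of combinatorial histone
    modification dynamics on a one-dimensional nucleosome lattice. Each
    nucleosome carries the states of its two H3 copies, giving a reduced
    four-state model (bivalent AR, monovalent AU and UR, unmodified UU)
    within a six-state framework. Marks are gained and lost by
    density-dependent recruitment and by spontaneous exchange (nucleation
    and histone turnover), and are diluted at replication once per cell
    cycle. The package provides the state-space algebra, a fast synchronous
    update engine, an exact transition-matrix oracle for small lattices,
    scenario drivers for domain formation, decay, nucleation-site
    localization and cell-cycle sweeps, and ensemble analytics (occupancy
    levels, front tracking, merge and equilibration times, domain profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, Software, StochasticSimulation
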