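Package: msabm
Title: Agent-Based Simulation of Multiple Sclerosis Lesion Formation and Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An on-lattice, stochastic agent-based model of multiple sclerosis
    lesion development in a two-dimensional section of central nervous system
    tissue. Primed T cells enter from a peripheral blood compartment, cross a
    permeable blood-brain barrier, are reactivated by perivascular macrophages,
    and degrade myelin under chemotaxis-biased random walks. Oligodendrocytes
    are modelled as 5x5 blocks of myelin sites whose integrated stress response
    is governed by two damage thresholds: one that halts remyelination and one
    that triggers apoptosis. The package provides a compiled simulation engine,
    scheduled relapse dynamics, in-silico treatment scenarios (blood-brain
    barrier permeability reduction, stress-tolerance enhancement, and full or
    partial oligodendrocyte restoration), replicate-averaged experiments, and
    sensitivity sweeps over permeability and stress tolerances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
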