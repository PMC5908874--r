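Package: clusternet
Title: Clustered Balanced Networks of Binary Neurons and Their Mean-Field Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and mean-field analysis of balanced networks of
    asynchronously updated binary neurons with clustered connectivity.
    Derives balanced-state synaptic weights and closed-form population
    rates, builds unit-level connectivity for unclustered, excitatory-
    clustered, jointly excitatory-inhibitory clustered, background-
    population and probability-clustered architectures, reduces any
    architecture to a population rate model, classifies fixed-point
    stability via the Jacobian (including critical inhibitory-to-
    excitatory time-constant ratios), maps multistable attractor
    landscapes and effective response functions, and runs event-driven
    binary-network simulations to quantify winnerless competition
    between cluster assemblies through the time variance of cluster
    activity rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
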