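Package: wormdev
Title: Spatio-Temporal Analysis of Developing Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the Caenorhabditis elegans neuronal network at
    discrete developmental stages from neuron birth times and soma positions,
    lifts published two-dimensional soma coordinates onto a cylindrical body
    model, and quantifies temporal and spatial wiring features: birth-time
    differences of connected neurons, embryonic versus post-embryonic
    connection phases, degree/birth-time coupling and hub formation,
    wiring-length classes (short/medium/long), functional-circuit assembly
    curves, and per-stage small-world indices. Every observable can be
    compared against identity-shuffle and Erdos-Renyi null ensembles with
    one-sample t-tests. Includes a seeded synthetic-connectome generator
    with planted temporal and spatial effects for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
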