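Package: gfcoal
Title: Graph Evaluation of Laplace-Transformed Coalescence-Time Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds the state-space graph of the structured coalescent for
    demographic models with population structure, unidirectional migration and
    at most one discrete event (a population split viewed backwards in time as
    a mass migration), and evaluates the Laplace transform (generating
    function) of the joint branch-length distribution directly on the graph.
    Discrete events are handled by a closed-form partial-fraction inverse
    Laplace transform over each collapsed path prefix. Probabilities of
    block-wise mutation configurations (the generalized block-wise site
    frequency spectrum, bSFS) are tabulated exactly by propagating truncated
    multivariate Taylor series through the computational graph with
    compensated summation, and cross-checked by a built-in Monte-Carlo
    structured-coalescent simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), Matrix, pracma, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'gfcoal-package.R'
    'model.R'
    'branch-types.R'
    'state-graph.R'
    'laplace.R'
    'taylor.R'
    'mutation-config.R'
    'bsfs.R'
    'mc.R'
    'run.R'
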