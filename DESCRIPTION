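Package: qubofs
Title: Mutual-Information QUBO Feature Selection for Small Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selects informative pixel subsets from small image
    classification datasets by formulating feature selection as a
    quadratic unconstrained binary optimization (QUBO) problem built
    from mutual-information importance and redundancy estimates.
    Includes hardware-motivated sparsifications (block subsampling,
    coupling thresholding, a sparsity-preserving linear Ising
    cardinality penalty), classical solvers (exhaustive enumeration and
    multi-restart simulated annealing), baseline selectors, and a
    convolutional decoder that scores selected pixel masks by test-set
    image reconstruction error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
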