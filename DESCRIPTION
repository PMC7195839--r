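Package: nlgrn
Title: Non-Linear Reverse Engineering of Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Rowan", "Hartley", email = "rowan.hartley@example.org",
           role = c("aut", "cre"))
Description: Infers gene regulatory networks from time-course expression data
    using a two-stage Gaussian graphical model forward search that selects both
    gene-to-gene regulations and regulations from pairwise non-linear terms
    (products of two genes' expression, standing in for protein heterodimers or
    synergistic co-regulation). The selected network parameterises a non-linear
    ordinary differential equation model whose coefficients are estimated by a
    real-coded genetic algorithm; fitted models are scored by simulation error
    and by perturbation-robustness statistics, and simplified by a greedy
    edge-deletion procedure. Includes a synthetic benchmark generator and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
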