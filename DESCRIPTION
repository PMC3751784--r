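Package: mcmcbpn
Title: Biological Process Networks from Perturbed Interaction Networks by MCMC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Summarizes a perturbed gene-gene interaction network as a small,
    non-redundant set of links between biological processes (a Biological
    Process Network, BPN). Candidate links between annotated processes explain
    the interactions they cross-annotate; a Bernoulli likelihood with link
    prior lambda, false-positive rate alpha and false-negative rate beta
    scores how well a link set accounts for the interactions whose endpoint
    genes are differentially expressed. Metropolis-Hastings MCMC over link
    sets and discrete parameter grids yields posterior link probabilities,
    reported above a threshold. Includes the Fisher-exact-test BPLN baseline,
    redundancy and replicate-consistency metrics, a synthetic-instance
    generator with planted links for validation, and readers for GMT gene
    sets, edge-list/SIF networks and per-gene p-value tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
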