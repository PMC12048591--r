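Package: gpdevo
Title: Evolutionary Modeling of Gene Product Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of gene product diversity generated by
    RNA-editing-type and splicing-type isoform modification. Provides
    steady-state solvers for isoform abundances under several modification
    topologies, a cis/trans genetic architecture mapping genotypes to
    conversion rates, Gaussian stabilizing and toxicity fitness functions with
    Kimura fixation probabilities, an origin-fixation Markov chain on the
    cis-genotypic value, an event-driven simulator of cis-trans regulatory
    coevolution, and a phylogenetic simulator of editing levels along a
    species tree with neighbor-joining tree recovery from editing-level
    distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
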