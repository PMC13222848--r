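Package: karyevol
Title: Chromosome Number and Sex Chromosome System Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("karyevol", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits a bounded continuous-time Markov chain of haploid autosome
    number and sex chromosome system (XY, XO, neo-XY) change on rooted,
    ultrametric phylogenies by Bayesian MCMC, replicated over a posterior
    sample of trees with random resolution of conflicting tip karyotype
    records. Samples stochastic character maps by endpoint-conditioned
    uniformization to count fission, autosomal-fusion and sex
    chromosome-autosome (SA) fusion events, and tests for an excess of
    SA-fusions against a duration-weighted random-fusion null expectation
    using 95% highest-posterior-density interval overlap. Includes a
    birth-death synthetic-data generator so the full pipeline is testable
    without external data.
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
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
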