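Package: StructFC
Title: Bayesian Functional Connectivity Informed by Structural Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint Bayesian modeling of functional brain connectivity from
    fMRI joint-activation counts with a structural-connectivity-informed
    prior built from probabilistic tractography counts. Implements the
    functional coherence statistic kappa and the ascendancy statistic tau,
    a Gibbs sampler with an embedded Metropolis step for the
    Dirichlet-multinomial / beta-binomial hierarchy, exceedance-probability
    edge calls, graph-theoretic network characterization (clustering
    coefficient, characteristic path length, degree-matched random-network
    null, small-world index, hub detection), and simulation studies of
    estimator bias, the kappa-correlation correspondence, and sensitivity
    to the structure-function link function.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
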