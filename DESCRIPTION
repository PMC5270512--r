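Package: mcmcDag
Title: Multi-Step Proposal MCMC for Bayesian Network Structure Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Metropolis-Hastings sampling over the space of directed acyclic
    graphs for discrete Bayesian networks, using a mixture proposal that draws
    a transition length t and performs t sequential uniform single-edge
    modifications (addition, deletion, reversal). For this proposal the
    Hastings ratio telescopes to the ratio of the endpoint neighbourhood
    sizes, so multi-step jumps cost no more to correct for than single steps.
    Scoring uses the BDeu Dirichlet-multinomial marginal likelihood with
    support for interventional (clamped) observations. The package ships an
    exact-enumeration posterior oracle for small networks, convergence
    diagnostics (edge posteriors, pairwise sum-of-squared-differences,
    score traces, unique-DAG counts, MAP and consensus graphs), and
    generators for ground-truth discrete networks, observational and
    interventional samples, and pooled two-network datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
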