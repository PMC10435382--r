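Package: treelfa
Title: Tree-Guided Latent Factor Allocation for Binary Diagnosis Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian topic modelling of binary individual-by-disease-code
    diagnosis matrices with an informative prior on topics derived from a
    medical ontology tree (treeLFA), together with its flat-prior variant
    (flatLFA) and a collapsed-Gibbs LDA baseline. Provides partially
    collapsed Gibbs sampling with the topic-weight vector integrated out,
    Gibbs-EM optimisation of the Dirichlet concentration, simulation of
    diagnosis datasets from the generative model, posterior post-processing
    (topic alignment, SNN/Louvain clustering of posterior topic samples,
    collapsing of near-empty topics), evaluation metrics (topic recovery
    error, Monte-Carlo held-out predictive likelihood, topic coherence,
    topic diversity, ontology concordance), and downstream utilities for
    genetic analyses (logit phenotype export, topic-to-code polygenic score
    combination, and a power simulation for association tests on combined
    binary traits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    scran
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
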