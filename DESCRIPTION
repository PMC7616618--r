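Package: antphylo
Title: Phylogenetic Comparative Tests of the Size-Complexity Hypothesis in Ants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for testing whether colony size drives the
    evolution of social complexity (multiple physical worker castes) across
    ants. Curates species-level social traits (colony size, effective queen
    mating frequency, queen number, caste counts, worker head-width variation),
    fits Bayesian phylogenetic mixed models, phylogenetic path analyses
    (d-separation, Fisher's C, CICc model averaging), correlated-evolution
    models for paired binary traits (independent vs dependent continuous-time
    Markov models compared by stepping-stone Bayes factors with reversible-jump
    MCMC rate estimation), and hidden-rate-model ancestral state
    reconstructions with node-level ancestral value regressions. Includes a
    synthetic trait simulator with known causal structure so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools,
    jsonlite
Config/testthat/edition: 3
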