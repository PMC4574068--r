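Package: selfsse
Title: State-Dependent Diversification and Mating-System Transitions on Dated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the "selfing as an evolutionary dead end"
    hypothesis on dated phylogenies with a binary mating-system character.
    Implements maximum-likelihood fitting of rate-constant and rate-variable
    diversification models on branching times (pure-birth, birth-death,
    diversity-dependent, and multi-rate Yule) with a simulation-based
    delta-AIC test; the two-rate Markov (Mk2) model of binary character
    evolution with exact pruning likelihoods, Bayesian MCMC over posterior
    tree samples, and marginal ancestral-state reconstruction; the binary
    state speciation and extinction (BiSSE) likelihood by adaptive ODE
    integration with a thirteen-model constraint suite, likelihood-ratio
    tests and credible-interval summaries; Bayes-factor statistics for
    monophyly hypotheses; mating-type coding rules; and seeded forward
    simulators (Yule, birth-death, BiSSE, Mk2) for synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
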