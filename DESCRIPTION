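Package: mplearn
Title: Markov Pattern Learning Models for Probability Learning Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and Bayesian analysis of two-alternative probability
    learning experiments with reinforcement-learning agents that search for
    temporal patterns. Implements the Markov pattern learning (MPL) model --
    a decay-reinforcement softmax learner whose expected utilities are
    conditioned on the last k outcomes -- together with its PVL (k = 0)
    restriction and a learning win-stay/lose-shift model. Provides outcome
    sequence generators (Bernoulli, repeating patterns, order-L Markov
    chains), synthetic cohort generators, hierarchical Bayesian fitting with
    the discrete memory parameter marginalized out, individual flat-prior
    fits with prior-to-posterior Kullback-Leibler identifiability metrics,
    k-fold cross-validation model comparison, and descriptive behavioural
    statistics (mean response curves, win-stay/lose-shift cross-correlation,
    and the nonmonotonic recency analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
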