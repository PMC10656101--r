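Package: diffjudge
Title: Sequential-Sampling Models of Perceptual Difficulty Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Drift-diffusion models of judging which of two perceptual
    decisions is easier. Implements a single-accumulator color
    drift-diffusion model with logistic collapsing bounds (Monte Carlo
    simulation and Fokker-Planck choice/RT densities), four competing 2D
    accumulator models of difficulty judgments (race, difference, two-step,
    absolute momentary evidence) with known-color, confidence-difference and
    controlled-duration variants, simulation-based maximum-likelihood
    fitting with Epanechnikov-kernel smoothed likelihoods, Bayesian model
    comparison (BIC, group BIC, random-effects exceedance probabilities),
    model and parameter recovery, and the reward-rate-optimal stopping
    policy obtained by backward induction over a belief-state Markov
    decision process. Includes generators for synthetic trial tables
    emulating two-stimulus color-coherence experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
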