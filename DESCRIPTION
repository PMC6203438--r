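Package: rewardDDM
Title: Reward-Biased Drift-Diffusion Modelling and Satisficing Analysis of
    Perceptual Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing perceptual decisions made under asymmetric
    reward: a drift-diffusion model extended with a momentary-evidence bias
    (me) and a decision-rule (starting-point) bias (z), with analytic
    first-passage choice probabilities and decision times, fast Monte-Carlo
    simulation (fixed and collapsing bounds), and single-trial
    likelihood-based session fitting with simulate-and-refit model
    comparison. Includes logistic psychometric characterisation with lapse
    and sequential-bias terms, reward-per-trial and reward-rate surfaces
    over the two bias parameters with optimality benchmarks (optima, 97%
    contours, patch orientation), a satisficing gradient-ascent learning
    model over those surfaces, and a synthetic session generator that
    emulates blocked reward contexts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
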