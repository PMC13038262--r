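Package: coopdyn
Title: Computational Modelling of Cooperation Dynamics in the Repeated
    Prisoner's Dilemma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the repeated Prisoner's Dilemma Game against a
    partner with a pre-determined cooperation schedule, fits a suite of
    eight generative choice models (baseline, win-stay/lose-shift, reward
    learning, inequality aversion, and social-reward models with static,
    basic, influence-based, and asymmetric belief updating) to
    trial-by-trial choice sequences by multi-start maximum likelihood,
    compares them with AICc and group-level random-effects Bayesian model
    selection (protected exceedance probability), validates the pipeline
    with model- and parameter-recovery analyses, extracts trial-by-trial
    latent variables (partner-cooperation expectation and intrinsic reward
    for reciprocity), and provides the post-hoc inferential layer (pooled
    two-sample t, JZS Bayes factor, Pearson correlation) used for group
    contrasts on a synthetic two-group cohort.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
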