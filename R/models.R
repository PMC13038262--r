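# Model suite: eight candidate generative models of cooperation in the
# repeated Prisoner's Dilemma, shared softmax / belief-update primitives,
# and the generative agent built on the compiled trial engine.
#
# Conventions fixed across the package: actions are coded 1 = cooperate,
# 0 = defect; the initial partner-cooperation expectation is p0 = 0.5; the
# reward-learning model starts both option values at 3 (the grand mean of
# the payoff entries); larger inverse temperature beta means more
# deterministic choice.

P0_DEFAULT <- 0.5
V0_DEFAULT <- 3.0

model_registry_tbl <- function() {
  tibble(
    model = c("M1_baseline", "M2_wsls", "M3_reward_rl", "M4_inequality",
              "M5_social_reward", "M6_social_rl", "M7_social_influence",
              "M8_social_asym_rl"),
    code = 1:8,
    params = list(
      "b", "epsilon", c("alpha", "beta"), c("phi", "nu", "beta"),
      c("omega", "beta"), c("alpha", "omega", "beta"),
      c("alpha", "kappa", "omega", "beta"),
      c("alpha_pos", "alpha_neg", "omega", "beta")),
    k = c(1L, 1L, 2L, 3L, 2L, 3L, 4L, 4L),
    has_belief = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    social = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

param_bounds_tbl <- function() {
  tibble(
    param = c("b", "epsilon", "alpha", "alpha_pos", "alpha_neg", "kappa",
              "beta", "omega", "phi", "nu"),
    lower = c(0, 0, 0, 0, 0, 0, 1e-3, 0, 0, 0),
    upper = c(1, 1, 1, 1, 1, 1, 20, 10, 5, 5)
  )
}

#' Candidate model registry
#'
#' One row per candidate model: identifier, free-parameter names, and the
#' number of free parameters `k` used in the AICc penalty.
#'
#' @param model Optional model id(s) (e.g. `"M8_social_asym_rl"`, or the
#'   shorthand `"M8"`) to subset to.
#' @return A tibble with columns `model`, `params` (list-column of
#'   parameter names), `k`, `has_belief`, `social`.
#' @examples
#' model_registry()
#' @export
model_registry <- function(model = NULL) {
  reg <- model_registry_tbl()
  if (is.null(model)) return(select(reg, -"code"))
  select(reg[match_model(model), ], -"code")
}

# Resolve full ids or "M1".."M8" shorthand to registry rows.
match_model <- function(model) {
  reg <- model_registry_tbl()
  short <- paste0("M", reg$code)
  idx <- match(model, reg$model)
  idx[is.na(idx)] <- match(model[is.na(idx)], short)
  if (anyNA(idx)) {
    abort(paste0("unknown model id(s): ",
                 paste(model[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Parameter bounds
#'
#' Box constraints used for multi-start maximum likelihood and for drawing
#' generating parameters: learning rates, `b`, `epsilon` and `kappa` in
#' \[0, 1\]; inverse temperature `beta` in \[1e-3, 20\]; social-reward
#' weight `omega` in \[0, 10\]; inequality-aversion weights `phi`, `nu` in
#' \[0, 5\].
#'
#' @param model Optional model id; when given, bounds are returned in the
#'   model's parameter order.
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
param_bounds <- function(model = NULL) {
  b <- param_bounds_tbl()
  if (is.null(model)) return(b)
  sig <- model_registry_tbl()$params[[match_model(model)]]
  b[match(sig, b$param), ]
}

# Validate a named parameter vector against a model signature; returns the
# values in engine order.
validate_params <- function(model, params) {
  i <- match_model(model)
  sig <- model_registry_tbl()$params[[i]]
  if (is.null(names(params)) || !setequal(names(params), sig)) {
    abort(paste0(model_registry_tbl()$model[i], " requires parameters {",
                 paste(sig, collapse = ", "), "}, got {",
                 paste(names(params), collapse = ", "), "}"))
  }
  v <- as.numeric(params[sig])
  b <- param_bounds(model)
  bad <- v < b$lower | v > b$upper
  if (any(bad)) {
    abort(paste0("parameter(s) out of bounds: ",
                 paste(sig[bad], collapse = ", ")))
  }
  setNames(v, sig)
}

## ---- primitives -----------------------------------------------------------

#' Softmax cooperation probability
#'
#' `q = 1 / (1 + exp(beta * (U_d - U_c)))`: the probability of cooperating
#' given the utilities of cooperation and defection.  Larger `beta` makes
#' choice more deterministic in the utility difference.
#'
#' @param U_c,U_d Utilities of cooperating and defecting.
#' @param beta Inverse temperature, > 0.
#' @return Cooperation probability in (0, 1).
#' @examples
#' softmax_coop_prob(2, 4, 1)
#' @export
softmax_coop_prob <- function(U_c, U_d, beta) {
  if (any(!is.finite(c(U_c, U_d)))) abort("utilities must be finite")
  if (any(beta <= 0)) abort("beta must be positive")
  # branch on the sign of the utility difference so that the complement
  # identity q(Uc, Ud) + q(Ud, Uc) = 1 holds bit-exactly
  ifelse(U_d >= U_c,
         1 / (1 + exp(beta * (U_d - U_c))),
         1 - 1 / (1 + exp(beta * (U_c - U_d))))
}

#' Baseline (bias-only) cooperation probability
#'
#' @param b Constant cooperation probability in \[0, 1\].
#' @return `b` itself; defection has probability `1 - b`.
#' @export
baseline_prob <- function(b) {
  check_prob(b, "b")
  b
}

#' Win-stay/lose-shift cooperation probability
#'
#' Repeat the previous choice with probability `1 - epsilon/2` after a win
#' (payoff 4 or 6) and `epsilon/2` after a loss (payoff 0 or 2); with no
#' history the probability is 0.5.
#'
#' @param epsilon Choice variability in \[0, 1\].
#' @param prev_own Previous own action (`"C"`/`"D"` or 1/0), or `NULL` on
#'   the first trial.
#' @param prev_payoff Previous own payoff, one of 0, 2, 4, 6.
#' @return Cooperation probability.
#' @examples
#' wsls_prob(0.2, "C", 6)  # stay with 0.9
#' @export
wsls_prob <- function(epsilon, prev_own = NULL, prev_payoff = NULL) {
  check_prob(epsilon, "epsilon")
  if (is.null(prev_own)) return(0.5)
  if (!prev_payoff %in% c(0, 2, 4, 6)) {
    abort("prev_payoff must be a payoff-matrix entry (0, 2, 4 or 6)")
  }
  rep_p <- if (prev_payoff %in% c(4, 6)) 1 - epsilon / 2 else epsilon / 2
  if (action_to_int(prev_own) == 1L) rep_p else 1 - rep_p
}

#' Delta-rule value update
#'
#' `V' = V + alpha * (R - V)`, applied to the chosen option's value only.
#'
#' @param V Current value.
#' @param R Obtained reward (tokens).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value.
#' @export
rl_update <- function(V, R, alpha) {
  check_prob(alpha, "alpha")
  V + alpha * (R - V)
}

#' Fehr-Schmidt inequality-aversion utilities
#'
#' Expected payoffs under partner-cooperation expectation `p` are
#' `c_self = 4p`, `c_other = 6 - 2p`, `d_self = 4p + 2`, `d_other = 2 - 2p`;
#' utilities subtract `phi` times disadvantageous and `nu` times
#' advantageous inequality.
#'
#' @param p Partner-cooperation expectation (fixed at 0.5 in the
#'   inequality-aversion model).
#' @param phi Aversion to disadvantageous inequality, >= 0.
#' @param nu Aversion to advantageous inequality, >= 0.
#' @return A tibble with columns `U_c`, `U_d`.
#' @examples
#' fehr_schmidt_utilities(0.5, 0.5, 0.25)
#' @export
fehr_schmidt_utilities <- function(p, phi, nu) {
  check_prob(p, "p")
  if (phi < 0 || nu < 0) abort("phi and nu must be non-negative")
  c_self <- 4 * p; c_other <- 6 - 2 * p
  d_self <- 4 * p + 2; d_other <- 2 - 2 * p
  tibble(
    U_c = c_self - phi * pmax(c_other - c_self, 0) - nu * pmax(c_self - c_other, 0),
    U_d = d_self - phi * pmax(d_other - d_self, 0) - nu * pmax(d_self - d_other, 0))
}

#' Social-reward utilities
#'
#' `U_c = p * (4 + omega)`, `U_d = 4p + 2`: cooperating is worth the
#' expected tokens plus an intrinsic bonus `omega` realised under mutual
#' cooperation; `p * omega` is the intrinsic reward for reciprocity.
#'
#' @param p Partner-cooperation expectation.
#' @param omega Social-reward weight, >= 0.
#' @return A tibble with columns `U_c`, `U_d`.
#' @export
social_reward_utilities <- function(p, omega) {
  check_prob(p, "p")
  if (any(omega < 0)) abort("omega must be non-negative")
  tibble(U_c = p * (4 + omega), U_d = 4 * p + 2)
}

#' Basic expectation update
#'
#' `p' = p + alpha * (P - p)` with `P = 1` if the partner cooperated.
#'
#' @param p Current expectation in \[0, 1\].
#' @param P Partner action, 1/0 (or `"C"`/`"D"`).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated expectation, in \[0, 1\] without clipping.
#' @export
expectation_update_basic <- function(p, P, alpha) {
  check_prob(p, "p"); check_prob(alpha, "alpha")
  p + alpha * (action_to_int(P) - p)
}

#' Asymmetric expectation update
#'
#' Prediction error `PE = P - p` is weighted by `alpha_pos` when positive
#' (better than expected) and `alpha_neg` when negative; a zero error
#' leaves the expectation unchanged.
#'
#' @inheritParams expectation_update_basic
#' @param alpha_pos,alpha_neg Learning rates for positive / negative
#'   prediction errors, each in \[0, 1\].
#' @return Updated expectation.
#' @examples
#' expectation_update_asymmetric(0.5, 1, 0.4, 0.2)  # 0.7
#' @export
expectation_update_asymmetric <- function(p, P, alpha_pos, alpha_neg) {
  check_prob(p, "p"); check_prob(alpha_pos, "alpha_pos")
  check_prob(alpha_neg, "alpha_neg")
  pe <- action_to_int(P) - p
  p + ifelse(pe > 0, alpha_pos * pe, ifelse(pe < 0, alpha_neg * pe, 0))
}

#' Influence-model expectation update
#'
#' Adds a second-order term to the basic update: the partner is assumed to
#' track the participant's own cooperation tendency, so the expectation
#' moves with `kappa * (Q - q')`, where `Q` is the own action and `q'` the
#' model-implied own cooperation probability this trial.  The result is
#' clipped to \[1e-3, 1 - 1e-3\].
#'
#' @inheritParams expectation_update_basic
#' @param Q Own action, 1/0 (or `"C"`/`"D"`).
#' @param q_prime Model-implied own cooperation probability.
#' @param kappa Second-order learning rate in \[0, 1\].
#' @return Updated, clipped expectation.
#' @export
expectation_update_influence <- function(p, P, Q, q_prime, alpha, kappa) {
  check_prob(p, "p"); check_prob(alpha, "alpha"); check_prob(kappa, "kappa")
  check_prob(q_prime, "q_prime")
  out <- p + alpha * (action_to_int(P) - p) +
    kappa * (action_to_int(Q) - q_prime)
  clip(out, 1e-3, 1 - 1e-3)
}

## ---- dispatch and simulation ----------------------------------------------

#' Per-trial cooperation probability for any model
#'
#' Dispatches over the eight candidate models given the model's current
#' state.  The same composition of primitives drives both likelihood
#' evaluation and generative simulation.
#'
#' @param model Model id.
#' @param params Named parameter vector matching the model's signature.
#' @param state A list; fields used depend on the model: `prev_own` and
#'   `prev_payoff` (win-stay/lose-shift), `V_c` and `V_d` (reward
#'   learning), `p` (belief models; defaults to 0.5 where fixed).
#' @return Cooperation probability.
#' @examples
#' trial_coop_prob("M5_social_reward", c(omega = 4, beta = 1), list(p = 0.5))
#' @export
trial_coop_prob <- function(model, params, state = list()) {
  i <- match_model(model)
  v <- validate_params(model, params)
  p <- state$p %||% P0_DEFAULT
  switch(as.character(i),
    "1" = baseline_prob(v[["b"]]),
    "2" = wsls_prob(v[["epsilon"]], state$prev_own, state$prev_payoff),
    "3" = {
      Vc <- state$V_c %||% V0_DEFAULT; Vd <- state$V_d %||% V0_DEFAULT
      softmax_coop_prob(Vc, Vd, v[["beta"]])
    },
    "4" = {
      u <- fehr_schmidt_utilities(p, v[["phi"]], v[["nu"]])
      softmax_coop_prob(u$U_c, u$U_d, v[["beta"]])
    },
    {
      u <- social_reward_utilities(p, v[["omega"]])
      softmax_coop_prob(u$U_c, u$U_d, v[["beta"]])
    })
}

# Assemble a latent-trace tibble from raw engine output, blanking fields a
# model does not define.
trace_tibble <- function(model, raw, params) {
  i <- match_model(model)
  reg <- model_registry_tbl()[i, ]
  T_ <- length(raw$q)
  out <- tibble(trial = seq_len(T_), q = raw$q, p = raw$p,
                U_c = raw$U_c, U_d = raw$U_d,
                V_c = raw$V_c, V_d = raw$V_d,
                q_prime = if (i == 7L) raw$q else rep(NA_real_, T_),
                pe = raw$pe,
                intrinsic = if (reg$social) raw$p * params[["omega"]]
                            else rep(NA_real_, T_))
  if (i %in% 1:3) out$p <- NA_real_
  if (i != 3L) { out$V_c <- NA_real_; out$V_d <- NA_real_ }
  if (i %in% 1:2) { out$U_c <- NA_real_; out$U_d <- NA_real_ }
  if (!reg$has_belief) out$pe <- NA_real_
  out
}

#' Simulate a model agent against a scheduled partner
#'
#' Samples each choice from the model's trial cooperation probability,
#' then applies the model's update with the scheduled partner action.
#' Latents are recorded before the choice.
#'
#' @param model Model id.
#' @param params Named parameter vector.
#' @param schedule Partner action sequence (`"C"`/`"D"`).
#' @param matrix A [payoff_matrix()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: actions, payoffs, and the
#'   latent trace (`q`, `p`, `U_c`, `U_d`, `V_c`, `V_d`, `q_prime`, `pe`,
#'   `intrinsic`); fields a model does not define are `NA`.
#' @examples
#' sched <- generate_partner_schedule(seed = 1)
#' sim <- simulate_agent("M8_social_asym_rl",
#'   c(alpha_pos = 0.4, alpha_neg = 0.2, omega = 2, beta = 2), sched,
#'   seed = 2)
#' mean(sim$own_action == "C")
#' @export
simulate_agent <- function(model, params, schedule,
                           matrix = payoff_matrix(), seed = NULL) {
  i <- match_model(model)
  v <- validate_params(model, params)
  if (length(schedule) == 0) abort("schedule must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  partner <- action_to_int(schedule)
  u <- runif(length(partner))
  raw <- cpp_simulate(i, unname(v), partner, u,
                      unname(unclass(matrix)[c("CC", "CD", "DC", "DD")]),
                      P0_DEFAULT, V0_DEFAULT)
  trace <- trace_tibble(model, raw, v)
  bind_cols(
    tibble(trial = seq_along(partner),
           own_action = int_to_action(raw$own),
           partner_action = int_to_action(partner),
           own_payoff = raw$own_payoff,
           partner_payoff = raw$partner_payoff),
    select(trace, -"trial"))
}
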