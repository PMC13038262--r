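# Task engine: payoff structure, partner schedule, probes, generic sessions.

#' Default repeated Prisoner's Dilemma payoff matrix
#'
#' Own-token payoffs indexed by (own action, partner action): mutual
#' cooperation pays 4, mutual defection 2, unilateral cooperation 0 and
#' unilateral defection 6.  The game is symmetric, so the partner's payoff
#' is the entry with roles swapped.
#'
#' @param cc,cd,dc,dd Own payoff for (own, partner) action pairs (C,C),
#'   (C,D), (D,C), (D,D).
#' @return A named numeric vector of class `coop_payoff` with entries
#'   `CC`, `CD`, `DC`, `DD`.
#' @examples
#' payoff_matrix()
#' @export
payoff_matrix <- function(cc = 4, cd = 0, dc = 6, dd = 2) {
  m <- c(CC = cc, CD = cd, DC = dc, DD = dd)
  if (any(m < 0) || any(m != round(m))) {
    abort("payoff entries must be non-negative integers")
  }
  structure(m, class = "coop_payoff")
}

#' Payoffs for one round of play
#'
#' @param own,partner Actions, `"C"` or `"D"` (or 1/0).
#' @param matrix A [payoff_matrix()].
#' @return A tibble with columns `own_payoff` and `partner_payoff`.
#' @examples
#' payoff("C", "D")   # cooperator gets 0, defector gets 6
#' @export
payoff <- function(own, partner, matrix = payoff_matrix()) {
  o <- action_to_int(own)
  p <- action_to_int(partner)
  key <- paste0(int_to_action(o), int_to_action(p))
  swap <- paste0(int_to_action(p), int_to_action(o))
  tibble(own_payoff = unname(unclass(matrix)[key]),
         partner_payoff = unname(unclass(matrix)[swap]))
}

#' Partner schedule configuration
#'
#' The partner's pre-determined behaviour: one 60-trial session with a
#' stable cooperation probability (default 0.78) and one 60-trial volatile
#' session of three 20-trial blocks at 20%/80%/20%, in either order.
#' Self-report probes occur every `probe_interval` trials.
#'
#' @param n_trials Total number of trials (default 120).
#' @param stable_prob Cooperation probability of the stable session.
#' @param volatile_probs Block cooperation probabilities of the volatile
#'   session.
#' @param volatile_block_len Trials per volatile block.
#' @param order `"stable_first"` or `"volatile_first"`.
#' @param probe_interval Trials between cooperativeness probes.
#' @return A list of class `coop_schedule_config`.
#' @export
schedule_config <- function(n_trials = 120L, stable_prob = 0.78,
                            volatile_probs = c(0.20, 0.80, 0.20),
                            volatile_block_len = 20L,
                            order = c("stable_first", "volatile_first"),
                            probe_interval = 15L) {
  order <- match.arg(order)
  check_prob(stable_prob, "stable_prob")
  check_prob(volatile_probs, "volatile_probs")
  if (!is_count(n_trials) || n_trials < 2) abort("n_trials must be a count >= 2")
  n_vol <- length(volatile_probs) * volatile_block_len
  if (n_trials != 2L * n_vol) {
    abort(paste0("n_trials (", n_trials, ") must equal twice the volatile ",
                 "session length (2 x ", n_vol, ")"))
  }
  if (n_trials %% probe_interval != 0) {
    abort("probe_interval must divide n_trials")
  }
  structure(list(n_trials = as.integer(n_trials), stable_prob = stable_prob,
                 volatile_probs = volatile_probs,
                 volatile_block_len = as.integer(volatile_block_len),
                 order = order, probe_interval = as.integer(probe_interval)),
            class = "coop_schedule_config")
}

# Per-trial cooperation probability implied by the schedule config.
schedule_probs <- function(cfg) {
  stable <- rep(cfg$stable_prob, cfg$n_trials / 2)
  volatile <- rep(cfg$volatile_probs, each = cfg$volatile_block_len)
  if (cfg$order == "stable_first") c(stable, volatile) else c(volatile, stable)
}

#' Generate the partner's pre-determined action sequence
#'
#' Each trial's action is an independent Bernoulli draw at that trial's
#' block cooperation probability.
#'
#' @param cfg A [schedule_config()].
#' @param seed Optional integer seed for a reproducible draw.
#' @return Character vector of `"C"`/`"D"` of length `cfg$n_trials`.
#' @examples
#' sched <- generate_partner_schedule(schedule_config(), seed = 1)
#' table(sched[1:60]) / 60   # close to 78% cooperation
#' @export
generate_partner_schedule <- function(cfg = schedule_config(), seed = NULL) {
  if (!inherits(cfg, "coop_schedule_config")) abort("cfg must be a schedule_config()")
  if (!is.null(seed)) set.seed(seed)
  pr <- schedule_probs(cfg)
  int_to_action(as.integer(runif(length(pr)) < pr))
}

#' Probe trial indices
#'
#' @inheritParams generate_partner_schedule
#' @return Integer vector of trial indices at which the cooperativeness
#'   probe is shown (multiples of `probe_interval`).
#' @examples
#' probe_trials(schedule_config())  # 15, 30, ..., 120
#' @export
probe_trials <- function(cfg = schedule_config()) {
  if (cfg$n_trials %% cfg$probe_interval != 0) {
    abort("probe_interval must divide n_trials")
  }
  seq(cfg$probe_interval, cfg$n_trials, by = cfg$probe_interval)
}

#' Run a session for an arbitrary agent policy
#'
#' A generic trial loop for policies outside the model suite (the model
#' agents use [simulate_agent()], which shares the same engine as the
#' likelihood).  A policy is a list with elements `prob(state, t)` giving
#' the cooperation probability before the choice and `update(state, own,
#' partner, payoff, t)` returning the next state; `init` is the initial
#' state (may be `NULL`).
#'
#' @param policy Policy list as described above.
#' @param schedule Partner action sequence (`"C"`/`"D"`).
#' @param matrix A [payoff_matrix()].
#' @param seed Optional integer seed.
#' @return A tibble of trial records: `trial`, `own_action`,
#'   `partner_action`, `own_payoff`, `partner_payoff`, and the pre-choice
#'   cooperation probability `q`.
#' @examples
#' always_c <- list(init = NULL, prob = function(s, t) 1,
#'                  update = function(s, own, partner, pay, t) s)
#' run_session(always_c, c("C", "D", "C"), seed = 1)
#' @export
run_session <- function(policy, schedule, matrix = payoff_matrix(),
                        seed = NULL) {
  if (length(schedule) == 0) abort("schedule must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  partner <- action_to_int(schedule)
  T_ <- length(partner)
  own <- integer(T_); own_pay <- numeric(T_); partner_pay <- numeric(T_)
  q <- numeric(T_)
  state <- policy$init
  u <- runif(T_)
  for (t in seq_len(T_)) {
    q[t] <- policy$prob(state, t)
    check_prob(q[t], "policy cooperation probability")
    own[t] <- as.integer(u[t] < q[t])
    pays <- payoff(own[t], partner[t], matrix)
    own_pay[t] <- pays$own_payoff
    partner_pay[t] <- pays$partner_payoff
    state <- policy$update(state, own[t], partner[t], own_pay[t], t)
  }
  tibble(trial = seq_len(T_), own_action = int_to_action(own),
         partner_action = int_to_action(partner),
         own_payoff = own_pay, partner_payoff = partner_pay, q = q)
}
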