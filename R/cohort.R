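# Synthetic two-group cohort: adolescents and adults with group-dependent
# asymmetric social-reward parameters, simulated sessions and probe
# self-reports, so the whole pipeline runs without any external data.

default_group_params <- function() {
  list(
    adolescent = list(alpha_pos = c(mean = 0.50, sd = 0.15),
                      alpha_neg = c(mean = 0.20, sd = 0.10),
                      omega     = c(mean = 1.2,  sd = 0.6),
                      beta      = c(mean = 2.0,  sd = 0.7)),
    adult      = list(alpha_pos = c(mean = 0.35, sd = 0.15),
                      alpha_neg = c(mean = 0.32, sd = 0.10),
                      omega     = c(mean = 2.0,  sd = 0.6),
                      beta      = c(mean = 1.4,  sd = 0.5)))
}

#' Synthetic-cohort configuration
#'
#' Defaults mirror the study conditions: 127 adolescents and 134 adults,
#' 120 trials each, session order counterbalanced, probes every 15 trials.
#' True parameters of the asymmetric social-reward model are drawn per
#' group from truncated normals (truncated at the parameter bounds); the
#' default group means encode the qualitative group differences (higher
#' `alpha_pos` and `beta`, lower `alpha_neg` and `omega` in adolescents).
#'
#' @param n_adolescents,n_adults Group sizes.
#' @param group_params Per-group list of `c(mean, sd)` for `alpha_pos`,
#'   `alpha_neg`, `omega`, `beta`; see `default_group_params` in the
#'   source for the defaults.
#' @param probe_noise_sd Standard deviation of the Gaussian read-out noise
#'   added to the belief before mapping to the 0-9 probe scale.
#' @param schedule A [schedule_config()] (its `order` field is overridden
#'   by counterbalancing when `counterbalance = TRUE`).
#' @param shared_sequence If `TRUE`, all participants with the same
#'   session order face one shared realised partner sequence; otherwise
#'   each participant gets an independent draw.
#' @param counterbalance Alternate session order across participants
#'   within each group.
#' @return A list of class `coop_cohort_config`.
#' @export
cohort_config <- function(n_adolescents = 127L, n_adults = 134L,
                          group_params = default_group_params(),
                          probe_noise_sd = 0.1,
                          schedule = schedule_config(),
                          shared_sequence = FALSE,
                          counterbalance = TRUE) {
  if (!is_count(n_adolescents) || !is_count(n_adults) ||
      n_adolescents < 1 || n_adults < 1) {
    abort("group sizes must be counts >= 1")
  }
  if (probe_noise_sd < 0) abort("probe_noise_sd must be >= 0")
  for (g in c("adolescent", "adult")) {
    gp <- group_params[[g]]
    if (!setequal(names(gp), c("alpha_pos", "alpha_neg", "omega", "beta"))) {
      abort("group_params must give alpha_pos, alpha_neg, omega, beta per group")
    }
    if (any(vapply(gp, function(x) x[["sd"]], 1) <= 0)) {
      abort("degenerate (sd <= 0) parameter distributions are rejected")
    }
  }
  structure(list(n_adolescents = as.integer(n_adolescents),
                 n_adults = as.integer(n_adults),
                 group_params = group_params,
                 probe_noise_sd = probe_noise_sd,
                 schedule = schedule,
                 shared_sequence = shared_sequence,
                 counterbalance = counterbalance),
            class = "coop_cohort_config")
}

draw_group_params <- function(n, gp) {
  b <- param_bounds("M8_social_asym_rl")
  out <- purrr::imap(gp, function(ms, nm) {
    bb <- b[b$param == nm, ]
    rtnorm(n, ms[["mean"]], ms[["sd"]], bb$lower, bb$upper)
  })
  as_tibble(out)[, c("alpha_pos", "alpha_neg", "omega", "beta")]
}

#' Generate a synthetic two-group cohort
#'
#' Per participant: draw true asymmetric social-reward parameters from the
#' group's truncated normals, simulate a full session with
#' [simulate_agent()] against a freshly drawn (or shared) partner
#' schedule, and generate probe self-reports as a noisy read-out of the
#' belief: `round(9 * clip(p_t + N(0, probe_noise_sd), 0, 1))`.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `coop_cohort`: list of tibbles
#'   `participants` (id, group, order, true parameters), `sessions` (long
#'   trial records), `probes`, `latents` (true latent traces), plus the
#'   `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_adolescents = 3, n_adults = 3),
#'                           seed = 1)
#' cohort$participants
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = NULL) {
  if (!inherits(cfg, "coop_cohort_config")) abort("cfg must be a cohort_config()")
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_adolescents + cfg$n_adults
  group <- rep(c("adolescent", "adult"), c(cfg$n_adolescents, cfg$n_adults))
  ids <- sprintf("S%03d", seq_len(n))
  params <- bind_rows(
    draw_group_params(cfg$n_adolescents, cfg$group_params$adolescent),
    draw_group_params(cfg$n_adults, cfg$group_params$adult))
  orders <- if (cfg$counterbalance) {
    unlist(lapply(c(cfg$n_adolescents, cfg$n_adults), function(m)
      rep(c("stable_first", "volatile_first"), length.out = m)))
  } else rep(cfg$schedule$order, n)
  sched_cfg <- function(ord) { s <- cfg$schedule; s$order <- ord; s }
  shared <- if (cfg$shared_sequence) {
    list(stable_first = generate_partner_schedule(sched_cfg("stable_first")),
         volatile_first = generate_partner_schedule(sched_cfg("volatile_first")))
  } else NULL
  pt <- probe_trials(cfg$schedule)
  per <- purrr::map(seq_len(n), function(j) {
    sched <- if (cfg$shared_sequence) shared[[orders[j]]]
             else generate_partner_schedule(sched_cfg(orders[j]))
    pv <- unlist(params[j, ])
    sim <- simulate_agent("M8_social_asym_rl", pv, sched)
    noise <- rnorm(length(pt), 0, cfg$probe_noise_sd)
    ratings <- as.integer(round(9 * clip(sim$p[pt] + noise, 0, 1)))
    list(
      session = tibble(participant_id = ids[j], group = group[j],
                       trial = sim$trial, own_action = sim$own_action,
                       partner_action = sim$partner_action,
                       own_payoff = sim$own_payoff,
                       partner_payoff = sim$partner_payoff),
      probes = tibble(participant_id = ids[j], trial = pt, rating = ratings),
      latents = bind_cols(tibble(participant_id = ids[j]),
                          select(sim, "trial", "q", "p", "U_c", "U_d",
                                 "pe", "intrinsic")))
  })
  structure(list(
    participants = bind_cols(tibble(participant_id = ids, group = group,
                                    order = orders), params),
    sessions = purrr::list_rbind(purrr::map(per, "session")),
    probes = purrr::list_rbind(purrr::map(per, "probes")),
    latents = purrr::list_rbind(purrr::map(per, "latents")),
    config = cfg), class = "coop_cohort")
}

#' @export
print.coop_cohort <- function(x, ...) {
  cat("<coop_cohort> ", nrow(x$participants), " participants (",
      sum(x$participants$group == "adolescent"), " adolescents, ",
      sum(x$participants$group == "adult"), " adults), ",
      x$config$schedule$n_trials, " trials each\n", sep = "")
  invisible(x)
}

# CSV writer preserving doubles to full precision.
write_table <- function(df, path) {
  df[] <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Export / read back a cohort as delimited tables
#'
#' Writes `sessions.csv`, `probes.csv` and `participants.csv`; the ground
#' truth (true parameters, session order) lives only in
#' `participants.csv`, so fitting code that consumes `sessions.csv` never
#' sees it.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Target directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "coop_cohort")) abort("cohort must be a coop_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("sessions.csv", "probes.csv", "participants.csv"))
  write_table(cohort$sessions, paths[1])
  write_table(cohort$probes, paths[2])
  write_table(cohort$participants, paths[3])
  invisible(setNames(paths, c("sessions", "probes", "participants")))
}

#' @rdname export_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) as_tibble(utils::read.csv(file.path(dir, f)))
  sessions <- rd("sessions.csv")
  probes <- rd("probes.csv")
  participants <- rd("participants.csv")
  probes$rating <- as.integer(probes$rating)
  list(sessions = sessions, probes = probes, participants = participants)
}
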