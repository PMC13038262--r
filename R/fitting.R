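# Maximum-likelihood fitting: per-session log-likelihood, multi-start
# bounded optimisation, AICc, and per-participant AICc differences.

# Columns the engine needs from a session table.
session_arrays <- function(trials) {
  if (nrow(trials) == 0) abort("trials must be non-empty")
  list(own = action_to_int(trials$own_action),
       partner = action_to_int(trials$partner_action),
       payoff = as.numeric(trials$own_payoff))
}

#' Log-likelihood of a choice sequence under one model
#'
#' Sums the log-probability each model assigns to the observed choice,
#' trial by trial, with the model's state updated from the observed own
#' and partner actions (not simulated ones).  Probabilities are clipped to
#' \[1e-10, 1 - 1e-10\] before the log, so the result is finite.
#'
#' @param model Model id.
#' @param params Named parameter vector.
#' @param trials Session tibble with columns `own_action`,
#'   `partner_action`, `own_payoff`.
#' @return The log-likelihood (<= 0).
#' @examples
#' trials <- simulate_agent("M1_baseline", c(b = 0.5),
#'                          rep(c("C", "D"), 60), seed = 1)
#' session_loglik("M1_baseline", c(b = 0.5), trials)  # 120 * log(0.5)
#' @export
session_loglik <- function(model, params, trials) {
  i <- match_model(model)
  v <- validate_params(model, params)
  a <- session_arrays(trials)
  -cpp_nll(i, unname(v), a$own, a$partner, a$payoff, P0_DEFAULT, V0_DEFAULT)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2L + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik Maximised log-likelihood `L`.
#' @param k Number of free parameters.
#' @param n Number of observations (trials).
#' @return The AICc value; lower is better.
#' @examples
#' aicc(120 * log(0.5), 1, 120)
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) abort("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Multi-start maximum-likelihood fit of one model to one session
#'
#' Bounded local optimisation (`optim`, L-BFGS-B) of the negative
#' log-likelihood from `n_starts` starting points drawn uniformly within
#' the parameter bounds; the best solution (highest log-likelihood) is
#' returned.  Deterministic given `seed`.
#'
#' @inheritParams session_loglik
#' @param n_starts Number of random starting points (the study protocol
#'   uses 500; smaller tiers trade exhaustiveness for speed).
#' @param seed Optional integer seed for the starting points.
#' @return An object of class `coop_fit`: a list with `model`, `params`
#'   (named MLE vector), `loglik`, `aicc`, `n_trials`, `n_starts_used`,
#'   `best_start_index`, `converged`.
#' @examples
#' trials <- simulate_agent("M1_baseline", c(b = 0.75),
#'                          rep("C", 120), seed = 1)
#' fit <- fit_mle("M1_baseline", trials, n_starts = 10, seed = 1)
#' tidy(fit)
#' @export
fit_mle <- function(model, trials, n_starts = 500L, seed = NULL) {
  if (!is_count(n_starts) || n_starts < 1) abort("n_starts must be >= 1")
  i <- match_model(model)
  a <- session_arrays(trials)
  b <- param_bounds(model)
  kk <- nrow(b)
  if (!is.null(seed)) set.seed(seed)
  # one row of uniforms per start (row-major) so that, at a fixed seed,
  # the first m starts are identical for any n_starts >= m
  starts <- matrix(runif(n_starts * kk), nrow = n_starts, byrow = TRUE)
  starts <- sweep(sweep(starts, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)
  obj <- function(par) cpp_nll(i, par, a$own, a$partner, a$payoff,
                               P0_DEFAULT, V0_DEFAULT)
  best <- NULL; best_idx <- NA_integer_; n_ok <- 0L
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[s, ], obj, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(factr = 1e4, maxit = 500L,
                           ndeps = rep(1e-6, kk))),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) { best <- res; best_idx <- s }
  }
  if (is.null(best)) {
    warn(paste0("all ", n_starts, " starts failed for ",
                model_registry_tbl()$model[i]))
    return(structure(list(model = model_registry_tbl()$model[i],
                          params = setNames(rep(NA_real_, kk), b$param),
                          loglik = NA_real_, aicc = NA_real_,
                          n_trials = length(a$own),
                          n_starts_used = n_starts,
                          best_start_index = NA_integer_, converged = FALSE),
                     class = "coop_fit"))
  }
  ll <- -best$value
  structure(list(model = model_registry_tbl()$model[i],
                 params = setNames(best$par, b$param),
                 loglik = ll,
                 aicc = aicc(ll, model_registry_tbl()$k[i], length(a$own)),
                 n_trials = length(a$own),
                 n_starts_used = n_starts,
                 best_start_index = best_idx,
                 converged = best$convergence == 0),
            class = "coop_fit")
}

#' @export
print.coop_fit <- function(x, ...) {
  cat("<coop_fit> ", x$model, "\n", sep = "")
  cat("  loglik ", format(x$loglik, digits = 6),
      "  AICc ", format(x$aicc, digits = 6),
      "  converged ", x$converged, "\n", sep = "")
  print(round(x$params, 4))
  invisible(x)
}

#' Fit candidate models to every participant in a session table
#'
#' @param sessions Long session tibble with columns `participant_id`,
#'   `trial`, `own_action`, `partner_action`, `own_payoff` (as produced by
#'   [generate_cohort()] or read back from its export).
#' @param models Model ids to fit, or `"all"` (default) for the full
#'   suite.
#' @param n_starts,seed Passed to [fit_mle()]; each participant x model
#'   fit receives its own child seed so results do not depend on
#'   evaluation order.
#' @return A tibble with one row per participant x model: `participant_id`,
#'   `model`, one column per parameter in the suite (`NA` when not in the
#'   model's signature), `loglik`, `aicc`, `converged`.
#' @export
fit_models <- function(sessions, models = "all", n_starts = 500L,
                       seed = NULL) {
  reg <- model_registry_tbl()
  if (identical(models, "all")) models <- reg$model
  idx <- match_model(models)
  ids <- unique(sessions$participant_id)
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(child_seeds(length(ids) * length(idx)),
                  nrow = length(ids))
  all_pars <- param_bounds_tbl()$param
  by_id <- split(sessions, factor(sessions$participant_id, levels = ids))
  rows <- purrr::map(seq_along(ids), function(pi) {
    trials <- arrange(by_id[[pi]], .data$trial)
    purrr::map(seq_along(idx), function(mi) {
      f <- fit_mle(reg$model[idx[mi]], trials, n_starts = n_starts,
                   seed = seeds[pi, mi])
      par_row <- setNames(as.list(rep(NA_real_, length(all_pars))), all_pars)
      par_row[names(f$params)] <- as.list(unname(f$params))
      tibble(participant_id = ids[pi], model = f$model, !!!par_row,
             loglik = f$loglik, aicc = f$aicc, converged = f$converged)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows
}

#' Per-participant AICc differences
#'
#' Subtracts each participant's minimum AICc across models, so the best
#' model per participant sits at exactly 0.
#'
#' @param fits Fits tibble from [fit_models()] (needs `participant_id`,
#'   `model`, `aicc`); every participant must carry the same model set.
#' @return The input with a `delta_aicc` column appended.
#' @export
delta_aicc <- function(fits) {
  n_models <- length(unique(fits$model))
  if (n_models < 2) abort("delta_aicc needs at least two models")
  counts <- count(fits, .data$participant_id)
  if (any(counts$n != n_models)) {
    abort("every participant must have an AICc entry for every model")
  }
  if (any(!is.finite(fits$aicc))) abort("non-finite AICc entries")
  fits |>
    group_by(.data$participant_id) |>
    mutate(delta_aicc = .data$aicc - min(.data$aicc)) |>
    ungroup()
}

#' Participant-by-model log-evidence matrix
#'
#' Model log-evidence is approximated by `-AICc / 2`, the conventional
#' information-criterion bridge into group-level Bayesian model selection.
#'
#' @inheritParams delta_aicc
#' @return A numeric matrix, rows = participants, columns = models.
#' @export
evidence_matrix <- function(fits) {
  wide <- fits |>
    select("participant_id", "model", "aicc") |>
    tidyr::pivot_wider(names_from = "model", values_from = "aicc")
  E <- as.matrix(select(wide, -"participant_id")) / -2
  rownames(E) <- as.character(wide$participant_id)
  if (any(!is.finite(E))) abort("evidence matrix has non-finite entries")
  E
}
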