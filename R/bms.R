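# Group-level random-effects Bayesian model selection: variational
# Dirichlet posterior over model frequencies, exceedance probability,
# Bayesian omnibus risk, protected exceedance probability.

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Random-effects group Bayesian model selection
#'
#' Treats the model identity of each participant as a random effect with a
#' Dirichlet prior over population model frequencies, updated variationally
#' from per-participant log-evidences (here `-AICc / 2`).  Exceedance
#' probability (the probability a model is the most frequent in the
#' population) is estimated from seeded Dirichlet draws (exact Beta-CDF
#' form when only two models are compared).  The Bayesian omnibus risk
#' (BOR) compares the random-effects model against the null of equal
#' frequencies by free energy, and the protected exceedance probability is
#' the mixture `pep = xp * (1 - bor) + bor / K`.
#'
#' @param E Log-evidence matrix, rows = participants, columns = models
#'   (see [evidence_matrix()]).
#' @param prior_alpha Dirichlet prior concentration per model (default 1,
#'   uniform).
#' @param n_draws Dirichlet draws for the exceedance-probability estimate.
#' @param seed Optional integer seed for those draws.
#' @param tol Convergence tolerance on the posterior concentrations.
#' @return An object of class `coop_bms`: list with `models`, `alpha`,
#'   `expected_freq`, `xp`, `bor`, `pep`, `F0`, `F1`, `n_subjects`.
#' @examples
#' E <- matrix(c(0, -3, 0, -4, 0, -5), nrow = 3, byrow = TRUE,
#'             dimnames = list(NULL, c("A", "B")))
#' group_bms(E, seed = 1)
#' @export
group_bms <- function(E, prior_alpha = 1, n_draws = 1e6L, seed = NULL,
                      tol = 1e-6) {
  if (!is.matrix(E) || nrow(E) < 2 || ncol(E) < 2) {
    abort("E must be a matrix with >= 2 participants and >= 2 models")
  }
  if (any(!is.finite(E))) abort("E must be finite")
  if (prior_alpha <= 0) abort("prior_alpha must be positive")
  K <- ncol(E); n <- nrow(E)
  models <- colnames(E) %||% paste0("model", seq_len(K))
  alpha0 <- rep(prior_alpha, K)
  alpha <- alpha0
  g <- matrix(0, n, K)
  repeat {
    elog <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(E, 2, elog, `+`)
    g <- exp(lu - apply(lu, 1, logsumexp))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  # exceedance probability
  if (K == 2L) {
    xp1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    xp <- c(xp1, 1 - xp1)
  } else {
    if (!is.null(seed)) set.seed(seed)
    draws <- matrix(rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                    nrow = n_draws)
    xp <- tabulate(max.col(draws, ties.method = "first"), K) / n_draws
  }
  # free energies: random-effects model vs equal-frequency null
  elog <- digamma(alpha) - digamma(sum(alpha))
  Sqf <- sum(lgamma(alpha)) - lgamma(sum(alpha)) - sum((alpha - 1) * elog)
  Sqm <- -sum(g * log(g + 1e-32))
  ELJ <- lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum((alpha0 - 1) * elog) + sum(g * sweep(E, 2, elog, `+`))
  F1 <- ELJ + Sqf + Sqm
  F0 <- sum(apply(E, 1, logsumexp)) - n * log(K)
  bor <- 1 / (1 + exp(F1 - F0))
  pep <- xp * (1 - bor) + bor / K
  structure(list(models = models,
                 alpha = setNames(alpha, models),
                 expected_freq = setNames(alpha / sum(alpha), models),
                 xp = setNames(xp, models),
                 bor = bor,
                 pep = setNames(pep, models),
                 F0 = F0, F1 = F1, n_subjects = n),
            class = "coop_bms")
}

#' @export
print.coop_bms <- function(x, ...) {
  cat("<coop_bms> ", x$n_subjects, " participants, ",
      length(x$models), " models, BOR = ", format(x$bor, digits = 4),
      "\n", sep = "")
  print(tidy(x), n = length(x$models))
  invisible(x)
}

#' Winning-model report
#'
#' Combines the group-level selection with per-participant AICc evidence:
#' the argmax-PEP model, each model's mean AICc difference, and the
#' fraction of participants best fit by each model.  Exact PEP ties are
#' reported as multiple winners, never silently broken.
#'
#' @param bms A [group_bms()] result.
#' @param fits Fits tibble carrying `delta_aicc` (see [delta_aicc()]).
#' @return A list with `winner` (character, length > 1 on a tie) and
#'   `summary`, a per-model tibble with `pep`, `xp`, `expected_freq`,
#'   `mean_delta_aicc`, `frac_best`.
#' @export
select_winning_model <- function(bms, fits) {
  if (!inherits(bms, "coop_bms")) abort("bms must be a group_bms() result")
  if (!"delta_aicc" %in% names(fits)) fits <- delta_aicc(fits)
  per_model <- fits |>
    group_by(.data$participant_id) |>
    mutate(is_best = .data$aicc == min(.data$aicc)) |>
    ungroup() |>
    group_by(.data$model) |>
    summarise(mean_delta_aicc = mean(.data$delta_aicc),
              frac_best = mean(.data$is_best), .groups = "drop")
  if (!setequal(per_model$model, bms$models)) {
    abort("fits and BMS result cover different model sets")
  }
  summary <- tibble(model = bms$models,
                    pep = unname(bms$pep),
                    xp = unname(bms$xp),
                    expected_freq = unname(bms$expected_freq)) |>
    left_join(per_model, by = "model") |>
    arrange(desc(.data$pep))
  winner <- summary$model[summary$pep == max(summary$pep)]
  list(winner = winner, summary = summary)
}
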