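# broom-style tidiers for the package's fitted objects.

#' Tidy a single-model fit
#'
#' @param x A `coop_fit` from [fit_mle()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `lower`, `upper`
#'   (the box constraints used in fitting).
#' @export
tidy.coop_fit <- function(x, ...) {
  b <- param_bounds(x$model)
  tibble(term = names(x$params), estimate = unname(x$params),
         lower = b$lower, upper = b$upper)
}

#' @rdname tidy.coop_fit
#' @return For `glance()`: a one-row tibble with `model`, `loglik`,
#'   `aicc`, `n_trials`, `k`, `n_starts_used`, `converged`.
#' @export
glance.coop_fit <- function(x, ...) {
  tibble(model = x$model, loglik = x$loglik, aicc = x$aicc,
         n_trials = x$n_trials,
         k = model_registry_tbl()$k[match_model(x$model)],
         n_starts_used = x$n_starts_used, converged = x$converged)
}

#' Tidy a group-level model-selection result
#'
#' @param x A `coop_bms` from [group_bms()].
#' @param ... Unused.
#' @return One row per model: Dirichlet concentration `alpha`, expected
#'   frequency, exceedance probability `xp`, protected exceedance
#'   probability `pep`.
#' @export
tidy.coop_bms <- function(x, ...) {
  tibble(model = x$models, alpha = unname(x$alpha),
         expected_freq = unname(x$expected_freq),
         xp = unname(x$xp), pep = unname(x$pep))
}

#' @rdname tidy.coop_bms
#' @return For `glance()`: a one-row tibble with `n_subjects`, `n_models`,
#'   `bor`, `F0`, `F1`.
#' @export
glance.coop_bms <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_models = length(x$models),
         bor = x$bor, F0 = x$F0, F1 = x$F1)
}

#' Tidy a confusion matrix
#'
#' @param x A `coop_confusion` from [model_recovery()].
#' @param ... Unused.
#' @return Long tibble: `generator`, `fitted`, `prop`, `n`.
#' @export
tidy.coop_confusion <- function(x, ...) {
  m <- x$matrix
  tidyr::expand_grid(generator = rownames(m), fitted = colnames(m)) |>
    mutate(prop = as.vector(t(m)),
           n = as.vector(t(x$counts)))
}

#' Tidy a parameter-recovery result
#'
#' @param x A `coop_recovery` from [parameter_recovery()].
#' @param ... Unused.
#' @return The per-parameter correlation tibble.
#' @export
tidy.coop_recovery <- function(x, ...) x$correlations
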