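# Validation of the fitting pipeline: model identifiability (confusion
# matrix over generator x fitted model) and parameter recovery (Pearson
# correlation between generating and recovered parameters).

# Generating distributions for recovery draws.  Parameters of the
# asymmetric social-reward model come from the cohort's group mixture
# (weighted by group size); parameters outside the cohort model use
# truncated normals of the same character, documented in the methods
# vignette.
extra_param_dists <- function() {
  list(b       = c(mean = 0.50, sd = 0.20),
       epsilon = c(mean = 0.50, sd = 0.20),
       alpha   = c(mean = 0.42, sd = 0.15),
       kappa   = c(mean = 0.30, sd = 0.15),
       phi     = c(mean = 0.50, sd = 0.30),
       nu      = c(mean = 0.50, sd = 0.30))
}

draw_generating_params <- function(model, n, cohort_cfg) {
  sig <- model_registry_tbl()$params[[match_model(model)]]
  gp <- cohort_cfg$group_params
  n_ado <- cohort_cfg$n_adolescents
  w_ado <- n_ado / (n_ado + cohort_cfg$n_adults)
  grp <- ifelse(runif(n) < w_ado, "adolescent", "adult")
  extra <- extra_param_dists()
  b <- param_bounds_tbl()
  cols <- lapply(sig, function(nm) {
    bb <- b[b$param == nm, ]
    if (nm %in% names(gp$adolescent)) {
      vapply(grp, function(g) {
        ms <- gp[[g]][[nm]]
        rtnorm(1, ms[["mean"]], ms[["sd"]], bb$lower, bb$upper)
      }, numeric(1), USE.NAMES = FALSE)
    } else {
      ms <- extra[[nm]]
      rtnorm(n, ms[["mean"]], ms[["sd"]], bb$lower, bb$upper)
    }
  })
  names(cols) <- sig
  as_tibble(cols)
}

# Simulate one synthetic dataset (one 120-trial session) from a model.
simulate_dataset <- function(model, params, schedule_cfg, order) {
  cfg <- schedule_cfg; cfg$order <- order
  sched <- generate_partner_schedule(cfg)
  simulate_agent(model, params, sched)
}

#' Model-identifiability (confusion-matrix) analysis
#'
#' For each generator model, simulates `n_datasets` synthetic sessions
#' with generating parameters drawn from the cohort distributions, fits
#' every candidate model to each dataset, and records the best-fitting
#' model by lowest AICc.  Session order alternates across datasets,
#' mirroring the counterbalanced design.
#'
#' @param models Model ids forming both the generator set and the
#'   candidate set (>= 2).
#' @param n_datasets Synthetic datasets per generator model.
#' @param cohort_cfg A [cohort_config()] supplying schedule and generating
#'   distributions.
#' @param n_starts Multi-start count per fit.
#' @param seed Integer seed; the whole analysis is reproducible from it.
#' @return An object of class `coop_confusion`: list with `matrix`
#'   (rows = generator, columns = fitted best model, rows sum to 1 over
#'   non-failed datasets), `counts`, `n_failed` per generator, and the
#'   call settings.
#' @export
model_recovery <- function(models, n_datasets = 100L,
                           cohort_cfg = cohort_config(), n_starts = 500L,
                           seed = NULL) {
  idx <- match_model(models)
  if (length(idx) < 2 && n_datasets > 0) {
    if (length(idx) < 1) abort("need at least one model")
  }
  mods <- model_registry_tbl()$model[idx]
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(child_seeds(length(mods) * n_datasets), nrow = length(mods))
  counts <- matrix(0L, length(mods), length(mods),
                   dimnames = list(generator = mods, fitted = mods))
  n_failed <- setNames(integer(length(mods)), mods)
  for (gi in seq_along(mods)) {
    pars <- draw_generating_params(mods[gi], n_datasets, cohort_cfg)
    for (d in seq_len(n_datasets)) {
      set.seed(seeds[gi, d])
      order <- if (d %% 2 == 1) "stable_first" else "volatile_first"
      sim <- simulate_dataset(mods[gi], unlist(pars[d, ]),
                              cohort_cfg$schedule, order)
      fit_seeds <- child_seeds(length(mods))
      aiccs <- vapply(seq_along(mods), function(fi) {
        f <- fit_mle(mods[fi], sim, n_starts = n_starts,
                     seed = fit_seeds[fi])
        if (f$converged) f$aicc else NA_real_
      }, numeric(1))
      if (all(is.na(aiccs))) {
        n_failed[gi] <- n_failed[gi] + 1L
      } else {
        best <- which.min(aiccs)
        counts[gi, best] <- counts[gi, best] + 1L
      }
    }
  }
  prop <- counts / pmax(rowSums(counts), 1L)
  structure(list(matrix = prop, counts = counts, n_failed = n_failed,
                 n_datasets = n_datasets, n_starts = n_starts),
            class = "coop_confusion")
}

#' @export
print.coop_confusion <- function(x, ...) {
  cat("<coop_confusion> ", x$n_datasets,
      " datasets per generator (rows = generator, cols = best fit)\n",
      sep = "")
  print(round(x$matrix, 3))
  if (any(x$n_failed > 0)) cat("failed datasets:", x$n_failed, "\n")
  invisible(x)
}

#' Parameter-recovery analysis
#'
#' Simulates `n_datasets` sessions from one model with generating
#' parameters drawn from the cohort distributions, refits the same model,
#' and correlates (Pearson) recovered with generating values per
#' parameter.
#'
#' @inheritParams model_recovery
#' @param model The model whose parameters are recovered.
#' @return An object of class `coop_recovery`: list with `correlations`
#'   (tibble `param`, `r`, `p`), `pairs` (tibble of generating and
#'   recovered values per dataset) and settings.  A zero-variance set of
#'   generating draws yields `NA` correlation for that parameter.
#' @export
parameter_recovery <- function(model, n_datasets = 100L,
                               cohort_cfg = cohort_config(),
                               n_starts = 500L, seed = NULL) {
  i <- match_model(model)
  mod <- model_registry_tbl()$model[i]
  sig <- model_registry_tbl()$params[[i]]
  if (!is.null(seed)) set.seed(seed)
  seeds <- child_seeds(n_datasets)
  pars <- draw_generating_params(mod, n_datasets, cohort_cfg)
  rows <- purrr::map(seq_len(n_datasets), function(d) {
    set.seed(seeds[d])
    order <- if (d %% 2 == 1) "stable_first" else "volatile_first"
    sim <- simulate_dataset(mod, unlist(pars[d, ]), cohort_cfg$schedule,
                            order)
    f <- fit_mle(mod, sim, n_starts = n_starts, seed = child_seeds(1))
    tibble(dataset = d, param = sig,
           true = as.numeric(pars[d, sig]),
           recovered = as.numeric(f$params[sig]),
           converged = f$converged)
  })
  pairs <- purrr::list_rbind(rows)
  correlations <- pairs |>
    filter(.data$converged) |>
    group_by(.data$param) |>
    summarise(
      r = if (sd(.data$true) == 0 || sd(.data$recovered) == 0) NA_real_
          else cor(.data$true, .data$recovered),
      p = if (sd(.data$true) == 0 || sd(.data$recovered) == 0) NA_real_
          else pearson_r(.data$true, .data$recovered)$p,
      n = n(), .groups = "drop") |>
    mutate(param = factor(.data$param, levels = sig)) |>
    arrange(.data$param) |>
    mutate(param = as.character(.data$param))
  structure(list(model = mod, correlations = correlations, pairs = pairs,
                 n_datasets = n_datasets, n_starts = n_starts),
            class = "coop_recovery")
}

#' @export
print.coop_recovery <- function(x, ...) {
  cat("<coop_recovery> ", x$model, ", ", x$n_datasets, " datasets\n",
      sep = "")
  print(x$correlations)
  invisible(x)
}
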