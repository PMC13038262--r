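# Latent-variable analyses: deterministic replay of fitted models over
# observed sessions, conditional-cooperation binning by runs of partner
# behaviour, and probe-rating normalisation.

#' Extract trial-by-trial latent variables from a fitted model
#'
#' Replays the observed session through the model deterministically (state
#' updated from the observed own and partner actions) and returns the
#' latent trace: belief `p`, utilities `U_c`/`U_d`, the model cooperation
#' probability `q`, prediction error `pe`, and the intrinsic reward for
#' reciprocity `intrinsic = p * omega`.  Models without a
#' partner-cooperation expectation (baseline, win-stay/lose-shift, reward
#' learning) are refused.
#'
#' @param fit A `coop_fit` from [fit_mle()], or a model id (then `params`
#'   must be supplied).
#' @param trials Session tibble with `own_action`, `partner_action`,
#'   `own_payoff`.
#' @param params Named parameter vector when `fit` is a model id.
#' @return A latent-trace tibble, one row per trial.
#' @examples
#' sched <- c("C", "C", "D", "C", "D")
#' sim <- simulate_agent("M8_social_asym_rl",
#'   c(alpha_pos = 0.4, alpha_neg = 0.2, omega = 2, beta = 2), sched,
#'   seed = 1)
#' extract_latents("M8_social_asym_rl", sim,
#'   params = c(alpha_pos = 0.4, alpha_neg = 0.2, omega = 2, beta = 2))$p
#' @export
extract_latents <- function(fit, trials, params = NULL) {
  if (inherits(fit, "coop_fit")) {
    model <- fit$model; params <- fit$params
  } else {
    model <- fit
    if (is.null(params)) abort("params must be supplied with a model id")
  }
  i <- match_model(model)
  if (i %in% 1:3) {
    abort(paste0(model_registry_tbl()$model[i], " has no partner-cooperation",
                 " expectation; latent extraction requires one of the",
                 " social-reward belief models"))
  }
  v <- validate_params(model, params)
  a <- session_arrays(trials)
  raw <- cpp_trace(i, unname(v), a$own, a$partner, a$payoff,
                   P0_DEFAULT, V0_DEFAULT)
  trace_tibble(model, raw, v)
}

#' Conditional means after runs of partner behaviour
#'
#' A trial `t` qualifies for condition (action `a`, run length `k`) when
#' the partner's actions at trials `t-1, ..., t-k` all equal `a` (and, with
#' `exact_run = TRUE`, the action at `t-k-1`, if any, differs).  Computes
#' the per-participant mean of the dependent variable over qualifying
#' trials: the cooperation indicator (`variable = "choice"`), the belief
#' `p`, or the intrinsic reward `intrinsic` (the latter two need
#' `latents`).
#'
#' @param sessions Long session tibble (`participant_id`, `trial`,
#'   `own_action`, `partner_action`; a `group` column is carried through).
#' @param variable `"choice"`, `"p"` or `"intrinsic"`.
#' @param k Run length(s), each >= 1.
#' @param partner_action Condition action(s), `"C"` and/or `"D"`.
#' @param latents Latent-trace tibble keyed by (`participant_id`, `trial`)
#'   as from [extract_latents()]; required unless `variable = "choice"`.
#' @param exact_run Require the run to be exactly `k` long rather than at
#'   least `k` (default: at least `k`, the larger-bin reading).
#' @return A tibble with one row per participant x condition:
#'   `participant_id` (and `group`), `variable`, `k`, `partner_action`,
#'   `mean` (`NA` when no trial qualifies), `n_trials`.
#' @export
conditional_means <- function(sessions, variable = c("choice", "p", "intrinsic"),
                              k = 1:3, partner_action = c("C", "D"),
                              latents = NULL, exact_run = FALSE) {
  variable <- match.arg(variable)
  if (any(k < 1)) abort("k must be >= 1")
  if (!all(partner_action %in% c("C", "D"))) abort("partner_action must be C/D")
  if (variable != "choice") {
    if (is.null(latents)) abort("latents are required unless variable = \"choice\"")
    sessions <- left_join(sessions,
                          select(latents, "participant_id", "trial",
                                 all_of(variable)),
                          by = c("participant_id", "trial"))
    if (anyNA(sessions[[variable]])) {
      abort("latents do not cover every session trial")
    }
  }
  has_group <- "group" %in% names(sessions)
  by_id <- split(sessions, sessions$participant_id)
  grid <- tidyr::expand_grid(k = as.integer(k), a = partner_action)
  out <- purrr::map(by_id, function(df) {
    df <- arrange(df, .data$trial)
    partner <- df$partner_action
    v <- switch(variable, choice = as.numeric(df$own_action == "C"),
                df[[variable]])
    T_ <- length(partner)
    purrr::map2(grid$k, grid$a, function(kk, aa) {
      if (T_ <= kk) qual <- logical(0)
      else {
        qual <- vapply((kk + 1):T_, function(t) {
          ok <- all(partner[(t - kk):(t - 1)] == aa)
          if (ok && exact_run && t - kk - 1 >= 1) {
            ok <- partner[t - kk - 1] != aa
          }
          ok
        }, logical(1))
      }
      idx <- which(qual) + kk
      tibble(participant_id = df$participant_id[1],
             group = if (has_group) df$group[1] else NA_character_,
             variable = variable, k = kk, partner_action = aa,
             mean = if (length(idx)) mean(v[idx]) else NA_real_,
             n_trials = length(idx))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (!has_group) out$group <- NULL
  out
}

#' Group summary of conditional means
#'
#' Across-participant mean and standard error per condition (participants
#' with no qualifying trial are excluded from that condition's summary).
#'
#' @param cond_tbl Output of [conditional_means()].
#' @param by Grouping columns in addition to the condition (default
#'   `"group"` when present).
#' @return A tibble with `mean`, `se`, `n_participants`, `n_excluded` per
#'   condition (x group).
#' @export
conditional_summary <- function(cond_tbl,
                                by = intersect("group", names(cond_tbl))) {
  cond_tbl |>
    group_by(across(all_of(c(by, "variable", "k", "partner_action")))) |>
    summarise(se = sd(.data$mean[!is.na(.data$mean)]) /
                sqrt(sum(!is.na(.data$mean))),
              n_participants = sum(!is.na(.data$mean)),
              n_excluded = sum(is.na(.data$mean)),
              mean = mean(.data$mean, na.rm = TRUE),
              .groups = "drop") |>
    select(all_of(by), "variable", "k", "partner_action", "mean", "se",
           "n_participants", "n_excluded")
}

#' Normalise probe ratings to the unit interval
#'
#' Ratings on the 0-9 probe scale are divided by 9.
#'
#' @param probes A probe tibble with a `rating` column, or a bare numeric
#'   vector of ratings.
#' @return The tibble with a `rating_norm` column appended, or the
#'   normalised numeric vector.
#' @examples
#' normalize_ratings(c(0, 5, 9))
#' @export
normalize_ratings <- function(probes) {
  r <- if (is.data.frame(probes)) probes$rating else probes
  if (any(!r %in% 0:9)) abort("ratings must be integers in 0..9")
  if (is.data.frame(probes)) mutate(probes, rating_norm = .data$rating / 9)
  else r / 9
}
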