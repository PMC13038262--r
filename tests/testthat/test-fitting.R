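test_that("session log-likelihood matches closed forms", {
  s <- random_session(120)
  expect_equal(session_loglik("M1_baseline", c(b = 0.5), s), 120 * log(0.5))
  all_c <- s; all_c$own_action <- "C"
  # clipped at 1 - 1e-10, so not exactly 0 but within the guard
  expect_equal(session_loglik("M1_baseline", c(b = 1), all_c), 0,
               tolerance = 1e-7)
  expect_error(session_loglik("M1_baseline", c(b = .5), s[0, ]), "non-empty")
})

test_that("engine log-likelihood equals the naive per-trial oracle", {
  set.seed(101)
  models <- model_registry()$model
  for (rep_ in 1:100) {
    m <- models[(rep_ - 1) %% 8 + 1]
    s <- random_session(T_ = sample(20:60, 1))
    par <- random_params(m)
    expect_equal(
      session_loglik(m, par, s),
      naive_loglik(m, par, action_to_int_test(s$own_action),
                   action_to_int_test(s$partner_action), s$own_payoff),
      tolerance = 1e-10)
  }
})

test_that("AICc follows the corrected formula and its limits", {
  expect_equal(aicc(-83.1777, 1, 120), 2 * 83.1777 + 2 + 4 / 118)
  expect_equal(aicc(-83.1777, 1, 120), 168.3893, tolerance = 1e-4)
  # correction term for k = 4, n = 120 is 40/115
  expect_equal(aicc(-10, 4, 120) - (-2 * -10 + 8), 40 / 115)
  # large-n limit tends to plain AIC
  expect_equal(aicc(-10, 2, 1e8), -2 * -10 + 4, tolerance = 1e-5)
  # strictly increasing in k at fixed L and n
  ks <- 1:6
  vals <- sapply(ks, function(k) aicc(-50, k, 120))
  expect_true(all(diff(vals) > 0))
  expect_error(aicc(-10, 4, 5), "n > k \\+ 1")
})

test_that("numeric MLE for the baseline model equals the sample mean", {
  set.seed(202)
  for (i in 1:100) {
    T_ <- 120
    n_c <- sample(1:(T_ - 1), 1)
    own <- sample(c(rep("C", n_c), rep("D", T_ - n_c)))
    s <- tibble::tibble(own_action = own,
                        partner_action = sample(c("C", "D"), T_, TRUE))
    s$own_payoff <- payoff(s$own_action, s$partner_action)$own_payoff
    s$trial <- seq_len(T_)
    f <- fit_mle("M1_baseline", s, n_starts = 3, seed = i)
    expect_equal(unname(f$params[["b"]]), n_c / T_, tolerance = 1e-6)
  }
  # the worked case: 90 cooperations in 120 trials
  s90 <- tibble::tibble(own_action = c(rep("C", 90), rep("D", 30)),
                        partner_action = rep("C", 120))
  s90$own_payoff <- payoff(s90$own_action, s90$partner_action)$own_payoff
  f90 <- fit_mle("M1_baseline", s90, n_starts = 5, seed = 1)
  expect_equal(unname(f90$params[["b"]]), 0.75, tolerance = 1e-6)
})

test_that("multi-start search is best-of monotone and self-consistent", {
  sched <- generate_partner_schedule(seed = 31)
  sim <- simulate_agent("M8_social_asym_rl",
                        c(alpha_pos = .45, alpha_neg = .2, omega = 1.8,
                          beta = 2), sched, seed = 32)
  lls <- sapply(c(1, 5, 20), function(ns)
    fit_mle("M8_social_asym_rl", sim, n_starts = ns, seed = 77)$loglik)
  expect_true(all(diff(lls) >= -1e-10))
  # the reported loglik is reproduced by evaluating the reported params
  f <- fit_mle("M8_social_asym_rl", sim, n_starts = 20, seed = 77)
  expect_equal(session_loglik("M8_social_asym_rl", f$params, sim), f$loglik,
               tolerance = 1e-10)
  expect_true(f$converged)
  expect_equal(f$n_starts_used, 20)
  expect_error(fit_mle("M8_social_asym_rl", sim, n_starts = 0), ">= 1")
})

test_that("asymmetric-model MLE is consistent on a long session", {
  truth <- c(alpha_pos = .45, alpha_neg = .2, omega = 1.8, beta = 2)
  sched <- rep(generate_partner_schedule(seed = 41), length.out = 6000)
  # long session: recycle the 120-trial schedule 50 times
  sim <- simulate_agent("M8_social_asym_rl", truth, sched, seed = 42)
  f <- fit_mle("M8_social_asym_rl", sim, n_starts = 25, seed = 43)
  expect_equal(unname(f$params), unname(truth), tolerance = 0.15)
})

test_that("fit_models and delta_aicc assemble the per-participant table", {
  sched <- generate_partner_schedule(seed = 51)
  sess <- dplyr::bind_rows(lapply(1:3, function(j) {
    sim <- simulate_agent("M6_social_rl", c(alpha = .3, omega = 2, beta = 2),
                          sched, seed = 50 + j)
    dplyr::bind_cols(tibble::tibble(participant_id = paste0("P", j)),
                     sim[, 1:5])
  }))
  fits <- fit_models(sess, models = c("M1_baseline", "M6_social_rl"),
                     n_starts = 5, seed = 1)
  expect_equal(nrow(fits), 6)
  expect_true(all(is.na(fits$omega[fits$model == "M1_baseline"])))
  expect_true(all(!is.na(fits$b[fits$model == "M1_baseline"])))
  d <- delta_aicc(fits)
  mins <- tapply(d$delta_aicc, d$participant_id, min)
  expect_true(all(mins == 0))
  # two-model hand case and permutation invariance
  toy <- tibble::tibble(participant_id = "a", model = c("x", "y"),
                        aicc = c(100, 103))
  expect_equal(delta_aicc(toy)$delta_aicc, c(0, 3))
  expect_equal(sort(delta_aicc(toy[2:1, ])$delta_aicc), c(0, 3))
  expect_error(delta_aicc(toy[1, ]), "at least two")
  expect_error(delta_aicc(dplyr::bind_rows(toy, toy[1, ])), "every model")
})
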