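m8_pars <- c(alpha_pos = 0.4, alpha_neg = 0.2, omega = 2, beta = 2)

test_that("replayed beliefs match the hand-iterated update", {
  # partner C, C, D, C, D from p0 = 0.5 with rates 0.4 / 0.2
  sched <- c("C", "C", "D", "C", "D")
  own <- c("C", "D", "C", "C", "D")
  s <- tibble::tibble(trial = 1:5, own_action = own, partner_action = sched,
                      own_payoff = payoff(own, sched)$own_payoff)
  tr <- extract_latents("M8_social_asym_rl", s, params = m8_pars)
  expect_equal(tr$p, c(0.5, 0.7, 0.82, 0.656, 0.7936), tolerance = 1e-12)
  # the belief after the last update (next-trial value) closes the chain
  last_p <- tr$p[5] - 0.2 * tr$p[5]
  expect_equal(last_p, 0.63488, tolerance = 1e-12)
  expect_equal(tr$intrinsic, tr$p * 2, tolerance = 1e-15)
})

test_that("latent extraction refuses models without a belief and handles limits", {
  s <- random_session(10)
  expect_error(extract_latents("M1_baseline", s, params = c(b = .5)),
               "no partner-cooperation expectation")
  expect_error(extract_latents("M3_reward_rl", s,
                               params = c(alpha = .2, beta = 1)),
               "no partner-cooperation expectation")
  # frozen learning: p stays at 0.5, intrinsic at omega / 2
  tr0 <- extract_latents("M8_social_asym_rl", s,
                         params = c(alpha_pos = 0, alpha_neg = 0,
                                    omega = 3, beta = 1))
  expect_true(all(tr0$p == 0.5))
  expect_true(all(tr0$intrinsic == 1.5))
  # omega = 0 kills the intrinsic reward
  trw <- extract_latents("M6_social_rl", s,
                         params = c(alpha = .3, omega = 0, beta = 1))
  expect_true(all(trw$intrinsic == 0))
})

test_that("replayed q matches the probabilities inside the likelihood", {
  set.seed(61)
  for (m in c("M4_inequality", "M5_social_reward", "M6_social_rl",
              "M7_social_influence", "M8_social_asym_rl")) {
    s <- random_session(60)
    par <- random_params(m)
    # keep choice probabilities away from the underflow tails, where the
    # complement 1 - q (used to rebuild the likelihood from the trace) is
    # itself the limiting approximation
    par[["beta"]] <- runif(1, 0.2, 2)
    if ("omega" %in% names(par)) par[["omega"]] <- runif(1, 0, 3)
    tr <- extract_latents(m, s, params = par)
    ll_from_trace <- sum(log(pmin(pmax(
      ifelse(s$own_action == "C", tr$q, 1 - tr$q), 1e-10), 1 - 1e-10)))
    expect_equal(ll_from_trace, session_loglik(m, par, s),
                 tolerance = 1e-12)
  }
})

test_that("conditional means reproduce hand-enumerated toy cases", {
  s <- tibble::tibble(participant_id = "p1", trial = 1:3,
                      own_action = c("C", "D", "C"),
                      partner_action = c("C", "C", "D"))
  t1 <- conditional_means(s, "choice", k = 1, partner_action = "C")
  expect_equal(t1$mean, 0.5)   # qualifying trials 2 and 3
  expect_equal(t1$n_trials, 2)
  t2 <- conditional_means(s, "choice", k = 2, partner_action = "C")
  expect_equal(t2$mean, 1)     # only trial 3
  expect_equal(t2$n_trials, 1)
  # no qualifying trial: explicit missing marker
  t3 <- conditional_means(s, "choice", k = 2, partner_action = "D")
  expect_true(is.na(t3$mean))
  expect_equal(t3$n_trials, 0)
})

test_that("k = 1 conditions partition trials 2..T", {
  set.seed(62)
  sched <- generate_partner_schedule(seed = 63)
  sim <- simulate_agent("M8_social_asym_rl", m8_pars, sched, seed = 64)
  s <- dplyr::bind_cols(tibble::tibble(participant_id = "p"), sim[, 1:5])
  tab <- conditional_means(s, "choice", k = 1)
  expect_equal(sum(tab$n_trials), 119)
  # exact-run counts never exceed the at-least-run counts
  tab_ex <- conditional_means(s, "choice", k = 2, exact_run = TRUE)
  tab_ge <- conditional_means(s, "choice", k = 2)
  expect_true(all(tab_ex$n_trials <= tab_ge$n_trials))
})

test_that("belief conditional means grow with longer cooperation runs", {
  sched <- rep("C", 40)
  sim <- simulate_agent("M8_social_asym_rl", m8_pars, sched, seed = 65)
  s <- dplyr::bind_cols(tibble::tibble(participant_id = "p"), sim[, 1:5])
  lat <- dplyr::bind_cols(tibble::tibble(participant_id = "p"),
                          sim[, c("trial", "p", "intrinsic")])
  tab <- conditional_means(s, "p", k = 1:3, partner_action = "C",
                           latents = lat)
  expect_true(all(diff(tab$mean[order(tab$k)]) >= 0))
  expect_error(conditional_means(s, "p"), "latents are required")
})

test_that("probe normalisation maps the 0-9 scale onto the unit interval", {
  expect_equal(normalize_ratings(9), 1)
  expect_equal(normalize_ratings(0), 0)
  expect_equal(normalize_ratings(5), 0.5556, tolerance = 1e-4)
  probes <- tibble::tibble(participant_id = "p", trial = c(15, 30),
                           rating = c(3L, 9L))
  out <- normalize_ratings(probes)
  expect_equal(out$rating_norm, c(1 / 3, 1))
  expect_error(normalize_ratings(10), "0..9")
  expect_error(normalize_ratings(c(2.5)), "0..9")
})
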