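test_that("softmax cooperation probability matches its closed form", {
  expect_equal(softmax_coop_prob(2, 2, 5), 0.5)
  expect_equal(softmax_coop_prob(0, 1, 1), 1 / (1 + exp(1)))
  expect_gt(softmax_coop_prob(3, 2, 50), 1 - 1e-10)
  # complement identity, exact
  for (b in c(0.5, 2, 10)) {
    expect_identical(softmax_coop_prob(1.3, 0.2, b) +
                       softmax_coop_prob(0.2, 1.3, b), 1)
  }
  expect_error(softmax_coop_prob(Inf, 0, 1), "finite")
  expect_error(softmax_coop_prob(1, 0, -1), "positive")
})

test_that("baseline and win-stay/lose-shift rules follow the verbal definitions", {
  expect_equal(baseline_prob(0.7), 0.7)
  expect_equal(baseline_prob(0), 0)
  expect_equal(baseline_prob(1), 1)
  expect_error(baseline_prob(1.4), "\\[0, 1\\]")

  expect_equal(wsls_prob(0.2, "C", 6), 0.9)   # stay after a win
  expect_equal(wsls_prob(0.2, "C", 0), 0.1)   # shift after a loss
  expect_equal(wsls_prob(0.2, "D", 2), 1 - 0.1)  # lost while defecting
  expect_equal(wsls_prob(1, "C", 6), 0.5)     # fully random
  expect_equal(wsls_prob(0.3, NULL), 0.5)     # first trial
  expect_error(wsls_prob(0.2, "C", 3), "payoff")
})

test_that("value and expectation updates match their difference equations", {
  expect_equal(rl_update(3, 6, 0.5), 4.5)
  expect_equal(rl_update(3, 6, 0), 3)
  expect_equal(rl_update(3, 6, 1), 6)

  expect_equal(expectation_update_basic(0.5, 1, 0.3), 0.65)
  expect_equal(expectation_update_basic(0.2, 0, 0), 0.2)
  expect_equal(expectation_update_basic(0.2, 1, 1), 1)

  expect_equal(expectation_update_asymmetric(0.5, 1, 0.4, 0.2), 0.7)
  expect_equal(expectation_update_asymmetric(0.5, 0, 0.4, 0.2), 0.4)
  # symmetric rates collapse to the basic rule
  for (p in c(0.1, 0.5, 0.9)) for (P in c(0, 1)) {
    expect_equal(expectation_update_asymmetric(p, P, 0.33, 0.33),
                 expectation_update_basic(p, P, 0.33))
  }

  # influence update: hand-composed example
  qp <- softmax_coop_prob(3, 4, 1)
  expect_equal(expectation_update_influence(0.5, 1, 1, qp, 0.3, 0.2),
               0.5 + 0.15 + 0.2 * (1 - qp), tolerance = 1e-12)
  expect_equal(expectation_update_influence(0.5, 1, 1, qp, 0.3, 0),
               expectation_update_basic(0.5, 1, 0.3))
  # Q = q' exactly: second-order term vanishes
  expect_equal(expectation_update_influence(0.4, 0, 1, 1, 0.2, 0.9),
               expectation_update_basic(0.4, 0, 0.2))
  # clipped into [1e-3, 1 - 1e-3]
  expect_equal(expectation_update_influence(0.99, 1, 1, 0, 1, 1), 1 - 1e-3)
})

test_that("utility functions reproduce the hand-evaluated payoff forms", {
  u <- fehr_schmidt_utilities(0.5, 0.5, 0.25)
  expect_equal(u$U_c, 2 - 0.5 * 3)
  expect_equal(u$U_d, 4 - 0.25 * 3)
  u0 <- fehr_schmidt_utilities(0.5, 0, 0)
  expect_equal(c(u0$U_c, u0$U_d), c(2, 4))

  s <- social_reward_utilities(0.5, 0)
  expect_equal(c(s$U_c, s$U_d), c(2, 4))
  s4 <- social_reward_utilities(0.5, 4)
  expect_equal(c(s4$U_c, s4$U_d), c(4, 4))
  expect_equal(softmax_coop_prob(s4$U_c, s4$U_d, 7), 0.5)  # indifference
  s0 <- social_reward_utilities(0, 3)
  expect_equal(c(s0$U_c, s0$U_d), c(0, 2))
})

test_that("trial_coop_prob dispatches consistently over the registry", {
  expect_equal(trial_coop_prob("M1_baseline", c(b = 0.7), list(p = 0.1)), 0.7)
  expect_equal(trial_coop_prob("M5_social_reward", c(omega = 4, beta = 2),
                               list(p = 0.5)), 0.5)
  # first-trial social model with omega = 0 reduces to softmax(2, 4, beta)
  expect_equal(trial_coop_prob("M8_social_asym_rl",
                               c(alpha_pos = .3, alpha_neg = .3, omega = 0,
                                 beta = 1.5), list(p = 0.5)),
               softmax_coop_prob(2, 4, 1.5))
  expect_error(trial_coop_prob("M8_social_asym_rl", c(alpha = .3, beta = 2)),
               "requires parameters")
  expect_error(trial_coop_prob("M6_social_rl",
                               c(alpha = 2, omega = 1, beta = 1)),
               "out of bounds")
  expect_error(trial_coop_prob("M99", c(b = .5)), "unknown model")
})

test_that("simulated agents respect degenerate limits and determinism", {
  sched <- generate_partner_schedule(seed = 9)
  # no learning: belief pinned at 0.5
  s <- simulate_agent("M8_social_asym_rl",
                      c(alpha_pos = 0, alpha_neg = 0, omega = 2, beta = 2),
                      sched, seed = 1)
  expect_true(all(s$p == 0.5))
  expect_equal(s$intrinsic, rep(1, 120))
  # near-deterministic limit: beta at bound, omega large
  s2 <- simulate_agent("M8_social_asym_rl",
                       c(alpha_pos = .5, alpha_neg = .5, omega = 10,
                         beta = 20), sched, seed = 2)
  expect_true(all(s2$own_action[s2$U_c - s2$U_d > 0.5] == "C"))
  # determinism
  s3a <- simulate_agent("M6_social_rl", c(alpha = .3, omega = 2, beta = 2),
                        sched, seed = 3)
  s3b <- simulate_agent("M6_social_rl", c(alpha = .3, omega = 2, beta = 2),
                        sched, seed = 3)
  expect_identical(s3a, s3b)
})

test_that("belief dynamics are monotone under consistent partners", {
  pars8 <- c(alpha_pos = .4, alpha_neg = .25, omega = 2, beta = 2)
  up <- simulate_agent("M8_social_asym_rl", pars8, rep("C", 200), seed = 1)
  expect_true(all(diff(up$p) >= 0))
  expect_gt(up$p[200], 0.999)
  down <- simulate_agent("M8_social_asym_rl", pars8, rep("D", 200), seed = 1)
  expect_true(all(diff(down$p) <= 0))
  expect_lt(down$p[200], 0.001)
  # beliefs stay in [0, 1] without clipping for the basic/asymmetric rules
  for (sd_ in 1:5) {
    sched <- generate_partner_schedule(seed = sd_)
    tr <- simulate_agent("M6_social_rl", c(alpha = .9, omega = 1, beta = 1),
                         sched, seed = sd_)
    expect_true(all(tr$p >= 0 & tr$p <= 1))
    expect_true(all(tr$q > 0 & tr$q < 1))
  }
})

test_that("symmetric asymmetric-rates runs are bit-identical to the basic rule", {
  sched <- generate_partner_schedule(seed = 21)
  a <- 0.37
  m6 <- simulate_agent("M6_social_rl", c(alpha = a, omega = 1.5, beta = 2.5),
                       sched, seed = 8)
  m8 <- simulate_agent("M8_social_asym_rl",
                       c(alpha_pos = a, alpha_neg = a, omega = 1.5,
                         beta = 2.5), sched, seed = 8)
  expect_identical(m6$p, m8$p)
  expect_identical(m6$q, m8$q)
  expect_identical(m6$own_action, m8$own_action)
  # intrinsic reward is exactly p * omega along the trace
  expect_identical(m8$intrinsic, m8$p * 1.5)
})
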