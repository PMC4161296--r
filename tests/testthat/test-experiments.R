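test_that("parallel success obeys the product law, stably for tiny p", {
  expect_equal(parallel_success(0.5, 2), 0.75)
  expect_equal(parallel_success(0, 1e6), 0)
  expect_equal(parallel_success(1, 3), 1)
  # independent oracle: truncated binomial series 1-(1-p)^t = tp - C(t,2)p^2 + ...
  p <- 1e-12; t <- 1e6
  series <- t * p - choose(t, 2) * p^2 + choose(t, 3) * p^3
  expect_equal(parallel_success(p, t), series, tolerance = 1e-9)
  expect_lt(abs(parallel_success(p, t) / 1e-6 - 1), 1e-5)
  # monotone in t
  expect_true(all(diff(parallel_success(0.01, c(1, 2, 10, 100))) > 0))
})

test_that("parallel ensembles match the exact product-law prediction", {
  ch <- neutral_chain(10, 4, 2)
  res <- parallel_experiment(ch, 8, t_values = c(1, 10), T_budget = 500,
                             n_meta = 400, seed = 31)
  expect_true(all(res$empirical >= res$ci_lo & res$empirical <= res$ci_hi))
  # t = 1 reduces to the per-search probability
  expect_equal(res$exact[res$t == 1], res$p_single[1])
  expect_true(all(diff(res$exact) > 0))
})

test_that("gambler's-ruin absorption matches closed form and linear solves", {
  # unbiased walk on 0..10 from 3: classic 1 - k/n
  n <- 11
  unb <- bd_chain(c(0, rep(0.5, n - 2), 0.5), c(0.5, rep(0, n - 2), 0.5),
                  c(0.5, rep(0.5, n - 2), 0), w = 0)
  expect_equal(absorption_before(unb, 3, 0, 10), 0.7)
  expect_equal(absorption_before(unb, 0, 0, 10), 1)
  expect_equal(absorption_before(unb, 10, 0, 10), 0)
  # neutral A=4, L=2: conditioned jump from 1 is 1/4 down
  ch <- neutral_chain(2, 4, 0)
  expect_equal(absorption_before(ch, 1, 0, 2), 1 / 4)
  # general chain vs absorbing linear solve
  ch6 <- neutral_chain(9, 4, 0)
  for (s in 2:7) {
    expect_equal(absorption_before(ch6, s, 1, 8),
                 ruin_absorb_solve(ch6, s, 1, 8), tolerance = 1e-12)
  }
})

test_that("stationary-mass estimates are exact and scale with m", {
  est <- stationary_time_estimate(10, 4, 1, 0)
  expect_equal(est$value, 1048576, tolerance = 1e-9)
  expect_identical(format(est$numerator), "1048576")
  expect_false(est$degenerate)
  est2 <- stationary_time_estimate(10, 4, 4, 1)
  expect_equal(est2$value, 1048576 / (4 * 31), tolerance = 1e-9)
  # doubling m halves the estimate exactly
  expect_equal(stationary_time_estimate(12, 4, 2, 1)$value,
               stationary_time_estimate(12, 4, 1, 1)$value / 2,
               tolerance = 1e-12)
  # whole space as target: degenerate
  expect_true(stationary_time_estimate(5, 4, 1, 5)$degenerate)
})

test_that("multi-peak experiment tracks the stationary-mass estimate", {
  res <- multi_target_experiment(10, 4, m = 4, w = 2, budget = 2e5,
                                 n_runs = 120, seed = 41)
  expect_gt(res$success_prob, 0.95)
  # within an order of magnitude of A^L / (m * ball)
  expect_lt(abs(log10(res$ratio)), 1)
  expect_error(multi_target_experiment(6, 4, m = 20, w = 3, budget = 100),
               "degenerate")
})

test_that("regeneration: restarts near the target succeed in polynomial time", {
  reg <- regeneration_experiment(c(8, 12), A = 4, k0 = 2, n_attempts = 4000,
                                 n_meta = 50, seed = 51)
  d <- tidy(reg)
  # simulated frequency agrees with the exact DP probability
  for (i in seq_len(nrow(d))) {
    ci <- qnorm(0.995) * sqrt(d$p_exact[i] * (1 - d$p_exact[i]) / 4000)
    expect_lt(abs(d$p_hat[i] - d$p_exact[i]), ci)
  }
  expect_true(all(d$ensemble_success >= 0.8))
  # k0 = 0: every attempt starts inside the target
  reg0 <- regeneration_experiment(c(8, 12), k0 = 0, n_attempts = 10, seed = 1)
  expect_true(all(tidy(reg0)$p_hat == 1))
  expect_error(regeneration_experiment(c(4, 8), k0 = 4), "k0 \\+ w < L")
})

test_that("regeneration succeeds polynomially while single searches cannot", {
  # per-attempt success decays polynomially (slope ~ -k0 on a clean grid) ...
  p <- vapply(c(16, 24, 32), function(L) {
    success_within(neutral_chain(L, 4, 0), 2, 20 * L^2)
  }, numeric(1))
  slope <- coef(lm(log(p) ~ log(c(16, 24, 32))))[[2]]
  expect_gt(slope, -2.6)
  expect_lt(slope, -1.4)
  # ... while the expected time of a single search from a random start grows
  # exponentially in L (drift-equilibrium start, same target)
  scan <- growth_scan(0, 4, c(16, 20, 24, 28, 32),
                      chain_builder = function(L, A, w) neutral_chain(L, A, 0))
  expect_equal(glance(scan)$verdict, "exponential")
  expect_gt(glance(scan)$exp_rate, 0)
})
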