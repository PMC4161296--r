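test_that("linear solve reproduces hand-solved small systems", {
  # L=1, A=4: geometric waiting with per-event success 1/3
  expect_equal(hitting_linear_solve(neutral_chain(1, 4, 0))$H[2], 3)
  # L=2, A=4: hand-solved 2x2 system
  H <- hitting_linear_solve(neutral_chain(2, 4, 0))$H
  expect_equal(H, c(0, 15, 18))
  # deterministic descent: H(k) = k - w
  det <- bd_chain(c(0, 1, 1, 1), c(1, 0, 0, 0), c(0, 0, 0, 0), w = 0)
  expect_equal(hitting_linear_solve(det)$H, c(0, 1, 2, 3))
})

test_that("forward sum matches the linear solve and its increments", {
  prof <- hitting_forward_sum(neutral_chain(2, 4, 0))
  expect_equal(prof$t[2:3], c(15, 3))
  expect_equal(prof$H[3], 18)
  # p_up == 0: independent geometric stages, t = 1/p_down
  stages <- bd_chain(c(0, 0.2, 0.5, 0.8), c(1, 0.8, 0.5, 0.2),
                     c(0, 0, 0, 0), w = 0)
  expect_equal(hitting_forward_sum(stages)$t[2:4], c(5, 2, 1.25))
})

test_that("forward sum and linear solve agree across chain families", {
  for (A in c(2, 4)) {
    for (L in c(5, 20, 60, 120)) {
      for (w in unique(c(0, floor(L / 4), floor(3 * L / 4)))) {
        ch <- neutral_chain(L, A, w)
        a <- hitting_forward_sum(ch)
        b <- hitting_linear_solve(ch)
        ks <- (w + 2):(L + 1)
        expect_equal(a$H[ks], b$H[ks], tolerance = 1e-9)
      }
    }
  }
  # selection chain too
  L <- 30
  ch <- selection_chain(L, 4, 3, (1.05)^(L - (0:L)), N = 40)
  expect_equal(hitting_forward_sum(ch)$H, hitting_linear_solve(ch)$H,
               tolerance = 1e-9)
})

test_that("expected times match the tail-sum of the finite-horizon DP", {
  # independent oracle: E[T_hit] = sum_{T>=0} P(T_hit > T), truncated where
  # the tail is provably below tolerance (P(T_hit > T) <= H/T)
  for (cfg in list(c(4, 4, 0), c(6, 4, 1), c(5, 2, 0))) {
    ch <- neutral_chain(cfg[1], cfg[2], cfg[3])
    start <- cfg[1]
    H <- hitting_forward_sum(ch)$H[start + 1]
    Tmax <- ceiling(H * 60)
    surv <- 1 - success_within(ch, start, 0:Tmax)
    expect_equal(sum(surv), H, tolerance = 1e-2)
  }
})

test_that("profiles are monotone and respond to transition changes correctly", {
  ch <- neutral_chain(30, 4, 5)
  H <- hitting_forward_sum(ch)$H
  expect_true(all(diff(H[7:31]) > 0))
  expect_true(all(H[1:6] == 0))
  # increasing any p_down decreases H pointwise (coupling, spot check)
  ch2 <- ch
  ch2$p_down[12] <- ch$p_down[12] * 1.5
  ch2$p_stay[12] <- 1 - ch2$p_down[12] - ch2$p_up[12]
  H2 <- hitting_forward_sum(bd_chain(ch2$p_down, ch2$p_stay, ch2$p_up,
                                     w = 5, A = 4))$H
  expect_true(all(H2[7:31] <= H[7:31] + 1e-9))
  expect_lt(H2[31], H[31])
})

test_that("log-space profile is finite and self-consistent at large L", {
  ch <- neutral_chain(100, 4, 50)
  prof <- hitting_forward_sum(ch)
  lt <- prof$log_t
  expect_true(all(is.finite(lt[52:101])))
  expect_true(all(is.finite(prof$log_H[52:101])))
  # t[k] p_down[k] - p_up[k] t[k+1] = 1, evaluated stably in log space;
  # past exp(30) the unit gap is below the ulp of the logs and the check
  # degenerates to the exp(-b) shift between the two logs
  for (k in 51:99) {
    a <- lt[k + 1] + log(ch$p_down[k + 1])
    b <- log(ch$p_up[k + 1]) + lt[k + 2]
    if (b < 16) {
      expect_equal(exp(b) * expm1(a - b), 1, tolerance = 1e-5)
    } else {
      expect_gte(a - b, -1e-12)
      expect_lt(a - b, exp(-min(b, 34)) + 1e-12)
    }
  }
  # far beyond double overflow the log values still behave
  big <- hitting_forward_sum(neutral_chain(1500, 4, 100))
  expect_true(is.finite(big$log_H[1501]))
  expect_gt(big$log_H[1501], 709)  # H itself would overflow
})

test_that("finite-horizon success probabilities match hand-computed values", {
  ch1 <- neutral_chain(1, 4, 0)
  expect_equal(success_within(ch1, 1, 0), 0)
  expect_equal(success_within(ch1, 1, c(1, 2)), c(1 / 3, 5 / 9))
  ch2 <- neutral_chain(2, 4, 0)
  expect_equal(success_within(ch2, 2, 2), 1 / 18)
  expect_equal(success_within(ch2, 0, 5), 1)
  # monotone in T and converging to 1
  probs <- success_within(ch2, 2, c(0, 1, 5, 20, 100, 1000))
  expect_true(all(diff(probs) >= 0))
  expect_equal(probs[6], 1, tolerance = 1e-3)
  # tail bound: P(T_hit > T) <= H(start)/T
  H2 <- hitting_forward_sum(ch2)$H[3]
  for (Tb in c(30, 60, 200)) {
    expect_lte(1 - success_within(ch2, 2, Tb), H2 / Tb + 1e-12)
  }
})

test_that("growth scans classify widths on either side of the threshold", {
  grid <- seq(20, 80, 10)
  wide <- growth_scan(0.85, 4, grid)
  narrow <- growth_scan(0.55, 4, grid)
  g_n <- glance(narrow)
  g_w <- glance(wide)
  expect_equal(g_n$verdict, "exponential")
  expect_gt(g_n$exp_rate, 0.05)
  expect_gt(g_n$r2_linear, 0.98)
  expect_equal(g_w$verdict, "polynomial")
  expect_lt(g_w$exp_rate, 0.05)
  expect_error(growth_scan(0.55, 4, c(20, 20, 30, 40, 50)), "distinct")
  expect_error(growth_scan(0.55, 4, c(20, 30, 40)), "at least 5")
})

test_that("exponential extrapolation projects the fitted growth law", {
  scan <- growth_scan(0.5, 4, seq(20, 80, 10))
  ext <- extrapolate_scan(scan, c(100, 1000))
  expect_true(all(diff(ext$log10_H) > 0))
  # at L = 1000 the time is astronomical
  expect_gt(ext$log10_H[2], 40)
})
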