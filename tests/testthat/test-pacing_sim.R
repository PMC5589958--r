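test_that("beat traces chain bit-for-bit and start at stimulus onset", {
  p <- params_at_pct(surr, 60)
  tr <- simulate_beats(surr, c(-86, 1, 7), n_beats = 3, params = p)
  expect_length(tr, 3)
  for (b in 1:2) {
    expect_identical(unname(attr(tr[[b]], "end_state")),
                     unname(stroboscopic_sample(tr[[b + 1]])))
  }
  expect_identical(tr[[1]]$t[1], 0)
  expect_identical(max(tr[[1]]$t), surr$pacing$cycle_length)
  expect_identical(unname(stroboscopic_sample(tr[[1]])), c(-86, 1, 7))
})

test_that("unstimulated surrogate stays at rest", {
  sys0 <- make_paced_surrogate_ap()
  sys0$pacing <- pacing_protocol(amplitude = 1e-12, duration = 1,
                                 cycle_length = 2000)
  p <- params_at_pct(sys0, 60)
  rest <- run_to_steady_state(sys0, c(-86, 1, 7), p, max_beats = 400)$state
  tr <- simulate_beats(sys0, rest, n_beats = 1, params = p)[[1]]
  expect_lt(max(tr$Vm) - min(tr$Vm), 1e-4)
})

test_that("per-beat evolution of the pulsed linear system matches closed form", {
  fl <- make_forced_linear(tau = 1000, T = 2000)
  ctl <- integrator_control(1e-10, 1e-12)
  x <- 7.5
  for (b in 1:5) {
    x_num <- poincare_map(fl, x, control = ctl)
    expect_equal(x_num, fl$known_features$closed_map(x), tolerance = 1e-8)
    x <- x_num
  }
  ss <- run_to_steady_state(fl, 0, max_beats = 200, control = ctl)
  expect_true(ss$converged)
  expect_equal(unname(ss$state), fl$known_features$fixed_point,
               tolerance = 1e-6)
})

test_that("identical inputs give bit-identical trajectories", {
  p <- params_at_pct(surr, 45)
  a <- poincare_map(surr, c(-86, 1, 6.5), params = p)
  b <- poincare_map(surr, c(-86, 1, 6.5), params = p)
  expect_identical(a, b)
  s1 <- run_to_steady_state(surr, c(-86, 1, 6.5), p, max_beats = 50)
  s2 <- run_to_steady_state(surr, c(-86, 1, 6.5), p, max_beats = 50)
  expect_identical(s1$state, s2$state)
})

test_that("steady-state detection is idempotent on a fixed point", {
  ctl <- integrator_control(1e-10, 1e-12)
  p <- params_at_pct(surr, 50)
  fp <- newton_shoot(surr, surr_attractor(50, "short")$state, params = p)
  ss <- run_to_steady_state(surr, fp$x, p, max_beats = 10, control = ctl)
  expect_true(ss$converged)
  expect_identical(ss$period, 1L)
  expect_lte(ss$beats_used, 2)
  expect_lt(ss$residual, 1e-8)
})

test_that("period-2 responses are flagged, not reported as period-1", {
  lm <- make_logistic_map(r = 3.2)   # past the period-doubling point
  ss <- run_to_steady_state(lm, 0.35, max_beats = 500)
  expect_true(ss$converged)
  expect_identical(ss$period, 2L)
  # the flagged orbit really is a 2-cycle, not a fixed point
  x <- unname(ss$state)
  expect_gt(abs(poincare_map(lm, x) - x), 0.1)
  expect_lt(abs(poincare_map(lm, x, k = 2) - x), 1e-7)
})

test_that("quasiperiodic responses fail convergence without error", {
  dl <- make_delayed_logistic_map(r = 2.1)  # past the torus birth
  ss <- run_to_steady_state(dl, c(0.5, 0.5), max_beats = 300)
  expect_false(ss$converged)
  expect_true(is.na(ss$period))
})

test_that("residual decays monotonically in the tail of a stable settle", {
  p <- params_at_pct(surr, 60)
  y <- c(-86, 1, 8.2)
  res <- numeric(40)
  prev <- y
  for (b in 1:40) {
    y <- poincare_map(surr, y, params = p)
    res[b] <- max(abs(y - prev))
    prev <- y
  }
  tail_res <- res[20:40]
  expect_true(all(diff(tail_res) < 1e-10))
})

test_that("APD90 of a converged beat is robust to integrator tolerances", {
  p <- params_at_pct(surr, 50)
  fp <- surr_attractor(50, "short")$state
  a <- apd90(simulate_beats(surr, fp, 1, params = p, dt_sample = 0.5,
                            control = integrator_control(1e-8, 1e-10))[[1]])
  b <- apd90(simulate_beats(surr, fp, 1, params = p, dt_sample = 0.5,
                            control = integrator_control(1e-10, 1e-12))[[1]])
  expect_lt(abs(a - b), 0.1)
})
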