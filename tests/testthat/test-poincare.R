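test_that("the stroboscopic map composes: P^2 = P o P", {
  ctl <- integrator_control(1e-10, 1e-12)
  p <- params_at_pct(surr, 55)
  x <- c(-86, 0.99, 6)
  two <- poincare_map(surr, x, k = 2, params = p, control = ctl)
  step <- poincare_map(surr, poincare_map(surr, x, params = p, control = ctl),
                       params = p, control = ctl)
  expect_lt(max(abs(two - step)), 1e-7)
})

test_that("monodromy of the pulsed linear system is exp(-kT/tau)", {
  fl <- make_forced_linear(tau = 1000, T = 2000)
  ctl <- integrator_control(1e-10, 1e-12)
  for (k in 1:2) {
    M <- monodromy(fl, 3, k = k, method = "variational", control = ctl)
    expect_equal(dim(M), c(1L, 1L))
    expect_equal(M[1, 1], exp(-2 * k), tolerance = 1e-7)
  }
})

test_that("zero dynamics give the identity monodromy", {
  still <- dynsys(kind = "forced_ode", state_names = c("a", "b"),
                  params = list(),
                  rhs_fn = function(t, y, p, stim) c(0, 0),
                  pacing = pacing_protocol(amplitude = 0, duration = 1,
                                           cycle_length = 100))
  M <- monodromy(still, c(1, 2))
  expect_equal(M, diag(2), tolerance = 1e-8)
})

test_that("finite-difference and variational monodromy routes agree", {
  ctl <- integrator_control(1e-10, 1e-12)
  p <- params_at_pct(surr, 50)
  states <- list(c(-86, 0.99, 6), c(-86, 0.99, 3), c(-40, 0.2, 1),
                 unname(surr_attractor(50, "short")$state))
  for (x in states) {
    Mf <- monodromy(surr, x, params = p, control = ctl)
    Mv <- monodromy(surr, x, params = p, method = "variational",
                    control = ctl)
    expect_lt(max(abs(Mf - Mv)) / max(abs(Mf)), 1e-4)
  }
  # map systems: FD against the analytic chain product
  dl <- make_delayed_logistic_map(r = 1.7)
  x <- c(0.41, 0.41)
  expect_equal(monodromy(dl, x, k = 3),
               monodromy(dl, x, k = 3, method = "variational"),
               tolerance = 1e-6)
})

test_that("multipliers come sorted by modulus and find rotations", {
  expect_equal(characteristic_multipliers(diag(c(0.5, -0.2))),
               as.complex(c(0.5, -0.2)))
  th <- 0.7; r <- 0.9
  R <- r * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m <- characteristic_multipliers(R)
  expect_equal(Mod(m), c(r, r), tolerance = 1e-12)
  expect_equal(abs(Arg(m[1])), th, tolerance = 1e-12)
})

test_that("Newton shooting converges in one step on the affine map", {
  fl <- make_forced_linear(tau = 1000, T = 2000)
  ctl <- integrator_control(1e-12, 1e-14)
  fp <- newton_shoot(fl, 40, control = ctl, tol = 1e-8)
  expect_true(fp$converged)
  expect_lte(fp$iterations, 1L)
  expect_equal(fp$x[["x"]], fl$known_features$fixed_point, tolerance = 1e-7)
})

test_that("shooting starting on a fixed point returns immediately", {
  lm <- make_logistic_map(r = 2.5)
  fp <- newton_shoot(lm, 1 - 1 / 2.5)
  expect_true(fp$converged)
  expect_identical(fp$iterations, 0L)
})

test_that("stable shooting results are confirmed by forward simulation", {
  p <- params_at_pct(surr, 50)
  fp <- newton_shoot(surr, surr_attractor(50, "short")$state, params = p)
  expect_true(fp$stable)
  # all multipliers strictly inside the unit circle: no trivial +1
  expect_true(all(Mod(fp$multipliers) < 1))
  y <- unname(fp$x) + c(1e-6, 1e-6, 1e-6)
  for (b in 1:50) y <- poincare_map(surr, y, params = p)
  expect_lt(max(abs(y - unname(fp$x))), 1e-6)
})

test_that("multiplier set is invariant under state-variable reordering", {
  perm <- c(3, 1, 2)                  # (Nai, Vm, h)
  inv <- order(perm)
  psys <- dynsys(kind = "forced_ode",
                 state_names = surr$state_names[perm],
                 params = surr$params,
                 rhs_fn = function(t, y, p, stim)
                   surr$rhs_fn(t, y[inv], p, stim)[perm],
                 pacing = surr$pacing,
                 state_scale = surr$state_scale[perm],
                 name = "surrogate_permuted")
  ctl <- integrator_control(1e-10, 1e-12)
  p <- params_at_pct(surr, 50)
  x <- unname(surr_attractor(50, "short")$state)
  m1 <- characteristic_multipliers(monodromy(surr, x, params = p,
                                             control = ctl))
  m2 <- characteristic_multipliers(monodromy(psys, x[perm], params = p,
                                             control = ctl))
  expect_equal(Mod(m1), Mod(m2), tolerance = 1e-5)
})

test_that("clamped systems expose a reduced monodromy", {
  p <- params_at_pct(surr, 50, nai_clamp = 6)
  M <- monodromy(surr, c(-86, 0.99, 6), params = p)
  expect_equal(dim(M), c(2L, 2L))
  fp <- newton_shoot(surr, c(-86, 0.99, 6), params = p)
  expect_true(fp$converged)
  expect_length(fp$multipliers, 2)
  expect_identical(fp$x[["Nai"]], 6)
})
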