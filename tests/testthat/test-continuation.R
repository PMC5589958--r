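test_that("constant-multiplier branches report no crossings", {
  fl <- make_forced_linear(tau = 1000, T = 2000)
  fp <- newton_shoot(fl, 5, control = integrator_control(1e-10, 1e-12))
  br <- continue_branch(fl, fp, "tau", c(900, 1200), initial_step = 30,
                        max_points = 20)
  df <- as.data.frame(br)
  expect_true(all(df$stable))
  expect_true(all(abs(diff(df$lead_mod)) < 0.05))   # smooth, no unit crossing
  expect_null(detect_crossings(br))
})

test_that("the logistic period doubling is localized at r = 3", {
  lm <- make_logistic_map(r = 2.8)
  fp <- newton_shoot(lm, 0.64)
  br <- continue_branch(lm, fp, "r", c(2.8, 3.2), initial_step = 0.05)
  cr <- detect_crossings(br)
  expect_true("PD" %in% cr$type)
  bp <- localize_bifurcation(lm, br, cr[cr$type == "PD", ][1, ],
                             tol_param = 1e-10)
  expect_equal(bp$param_value, 3, tolerance = 1e-6)
  expect_equal(Re(bp$critical_multiplier), -1, tolerance = 1e-6)
})

test_that("the delayed-logistic torus birth is localized at r = 2", {
  dl <- make_delayed_logistic_map(r = 1.8)
  fp <- newton_shoot(dl, c(0.45, 0.45))
  br <- continue_branch(dl, fp, "r", c(1.8, 2.2), initial_step = 0.05)
  cr <- detect_crossings(br)
  expect_true("NS" %in% cr$type)
  bp <- localize_bifurcation(dl, br, cr[cr$type == "NS", ][1, ],
                             tol_param = 1e-10)
  expect_equal(bp$param_value, 2, tolerance = 1e-6)
  expect_equal(Mod(bp$critical_multiplier), 1, tolerance = 1e-6)
  expect_gt(abs(Im(bp$critical_multiplier)), 1e-3)
})

test_that("the normal-form fold is rounded and pinned at mu = 0", {
  sn <- make_sn_normal_form(mu = -0.25)
  fp <- newton_shoot(sn, -0.5)
  br <- continue_branch(sn, fp, "mu", c(-0.3, 0.05), initial_step = 0.02)
  pr <- vapply(br$points, `[[`, numeric(1), "param")
  # the branch turns: parameter direction reverses at the fold
  expect_true(any(diff(pr) > 0) && any(diff(pr) < 0))
  cr <- detect_crossings(br)
  expect_true("SN" %in% cr$type)
  bp <- localize_bifurcation(sn, br, cr[cr$type == "SN", ][1, ])
  expect_equal(bp$param_value, 0, tolerance = 1e-9)
  # both sides of the fold: multipliers 1 -+ 2 sqrt(-mu)
  st <- vapply(br$points, `[[`, logical(1), "stable")
  expect_true(any(st) && any(!st))
})

test_that("re-running continuation backwards reproduces the bifurcation", {
  lm <- make_logistic_map(r = 3.15)
  # seed on the far side, walk back down through the PD
  fp <- newton_shoot(lm, 1 - 1 / 3.15)
  br <- continue_branch(lm, fp, "r", c(2.8, 3.15), initial_step = -0.05)
  cr <- detect_crossings(br)
  bp <- localize_bifurcation(lm, br, cr[cr$type == "PD", ][1, ],
                             tol_param = 1e-10)
  expect_equal(bp$param_value, 3, tolerance = 1e-6)
})

test_that("stability flips along a branch occur only at flagged crossings", {
  sn <- make_sn_normal_form(mu = -0.25)
  fp <- newton_shoot(sn, -0.5)
  br <- continue_branch(sn, fp, "mu", c(-0.3, 0.05), initial_step = 0.02)
  st <- vapply(br$points, `[[`, logical(1), "stable")
  flips <- which(diff(st) != 0)
  cr <- detect_crossings(br)
  for (f in flips) {
    expect_true(any(abs(cr$i - f) <= 1),
                label = sprintf("flip at %d has a flagged crossing", f))
  }
})

test_that("past the bare fold the normal form diverges (no coexisting attractor)", {
  sn <- make_sn_normal_form(mu = -0.25)
  fp <- newton_shoot(sn, -0.5)
  br <- continue_branch(sn, fp, "mu", c(-0.3, 0.05), initial_step = 0.02)
  cr <- detect_crossings(br)
  bp <- localize_bifurcation(sn, br, cr[cr$type == "SN", ][1, ])
  out <- post_bifurcation_transition(sn, bp, "mu", side = +1, delta = 0.01,
                                     max_beats = 500)
  expect_true(out$diverged)
})

test_that("surrogate short-AP branch folds and the fold is localized", {
  p <- params_at_pct(surr, 90)
  fp <- newton_shoot(surr, surr_attractor(90, "short")$state, params = p)
  br <- continue_branch(surr, fp, "pctGKr", c(5, 95), initial_step = -3,
                        max_points = 80, stop_mult = 10)
  cr <- detect_crossings(br)
  expect_true("SN" %in% cr$type)
  sn1 <- localize_bifurcation(surr, br, cr[cr$type == "SN", ][1, ])
  expect_gt(sn1$param_value, 10)
  expect_lt(sn1$param_value, 30)
  expect_equal(Mod(sn1$critical_multiplier), 1, tolerance = 5e-3)
  # past the fold, the orbit must land on the coexisting attractor:
  # the repolarisation-failure response
  out <- post_bifurcation_transition(surr, sn1, "pctGKr", side = -1,
                                     delta = 1)
  expect_identical(out$class, "LAVO")
})
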