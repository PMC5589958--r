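# Protocol-level behaviour on the bistable surrogate. Narrow sweep windows
# around the two folds keep these deterministic checks quick; the full-range
# sweep/continuation cross-validation lives in the acceptance suite.

test_that("down-sweep leaves the short-AP branch only past its fold", {
  start <- surr_attractor(30, "short")$state
  sw <- hysteresis_sweep(surr, 30, 14, step = 1, state0 = start,
                         max_beats = 2500)
  expect_identical(sw$class[1], "noEAD")
  tr_down <- sweep_transition(sw)
  expect_false(is.na(tr_down))
  expect_identical(sw$class[sw$param == tr_down], "LAVO")
  # transition lies in (14, 30): the short branch persists below 25
  expect_lt(tr_down, 25)
  expect_gt(tr_down, 14)
})

test_that("up-sweep carries the failure response far beyond the down transition", {
  start <- surr_attractor(80, "lavo")$state
  sw <- hysteresis_sweep(surr, 80, 92, step = 1, state0 = start,
                         max_beats = 2500)
  expect_identical(sw$class[1], "LAVO")
  tr_up <- sweep_transition(sw)
  expect_false(is.na(tr_up))
  expect_identical(sw$class[sw$param == tr_up], "noEAD")
  expect_gt(tr_up, 80)      # hysteresis: transition far above the down-sweep's
})

test_that("monostable surrogate sweeps identically in both directions", {
  start <- run_to_steady_state(surr_mono, c(-86, 1, 7),
                               params_at_pct(surr_mono, 70),
                               max_beats = 1200)$state
  dn <- hysteresis_sweep(surr_mono, 70, 60, step = 2, state0 = start,
                         max_beats = 1200)
  start_up <- run_to_steady_state(surr_mono, c(-86, 1, 7),
                                  params_at_pct(surr_mono, 60),
                                  max_beats = 1200)$state
  up <- hysteresis_sweep(surr_mono, 60, 70, step = 2, state0 = start_up,
                         max_beats = 1200)
  expect_true(all(dn$class == "noEAD"))
  expect_true(all(up$class == "noEAD"))
  m <- merge(dn, up, by = "param")
  expect_equal(m$apd90.x, m$apd90.y, tolerance = 1e-3)
  expect_equal(m$Nai.x, m$Nai.y, tolerance = 1e-5)
})

test_that("the carry-over contract is what produces hysteresis", {
  # with carry-over, pct 50 reached from below stays on the failure branch;
  # a fresh control start at the same parameters lands on the short branch
  carried <- surr_attractor(50, "lavo")$state
  sc_carried <- settle_and_classify(surr, carried, params_at_pct(surr, 50),
                                    max_beats = 10)
  fresh <- run_to_steady_state(surr, c(-86, 1, 7), params_at_pct(surr, 50),
                               max_beats = 1500)
  sc_fresh <- settle_and_classify(surr, fresh$state, params_at_pct(surr, 50),
                                  max_beats = 10)
  expect_identical(sc_carried$class, "LAVO")
  expect_identical(sc_fresh$class, "noEAD")
})

test_that("census finds two attractors inside the window and one outside", {
  bank <- default_init_bank(surr, n_nai = 4)
  inside <- multistability_census(surr, 50, bank, max_beats = 1500)
  expect_identical(inside$order, 2L)
  expect_setequal(inside$classes, c("noEAD", "LAVO"))
  below <- multistability_census(surr, 8, bank, max_beats = 1500)
  expect_identical(below$order, 1L)
  expect_identical(below$classes, "LAVO")
})

test_that("census order never decreases when the bank grows", {
  small <- default_init_bank(surr, n_nai = 2)
  big <- c(small, default_init_bank(surr, n_nai = 5))
  o_small <- multistability_census(surr, 50, small, max_beats = 1500,
                                   classify = FALSE)$order
  o_big <- multistability_census(surr, 50, big, max_beats = 1500,
                                 classify = FALSE)$order
  expect_gte(o_big, o_small)
})

test_that("sodium perturbations switch attractors only across the boundary", {
  p <- params_at_pct(surr, 50)
  short_fp <- surr_attractor(50, "short")$state
  same <- perturb_and_settle(surr, short_fp, 0, params = p)
  expect_identical(same$class, "noEAD")
  small <- perturb_and_settle(surr, short_fp, -1, params = p)
  expect_identical(small$class, "noEAD")
  # dropping the slow sodium far below the saddle leaves the short basin
  big <- perturb_and_settle(surr, short_fp, -5.5, params = p)
  expect_identical(big$class, "LAVO")
})

test_that("clamping the slow variable collapses the bistable window", {
  res <- nai_fixed_analysis(surr, nai_values = c(6, 0.2),
                            pct_values = 50,
                            init_bank = default_init_bank(surr, n_nai = 4),
                            max_beats = 1500)
  free <- res[is.na(res$nai_clamp), ]
  clamped_mid <- res[!is.na(res$nai_clamp) & res$nai_clamp == 6, ]
  clamped_low <- res[!is.na(res$nai_clamp) & res$nai_clamp == 0.2, ]
  expect_identical(free$order, 2L)
  expect_identical(clamped_mid$order, 1L)     # short-AP only
  expect_identical(clamped_mid$classes, "noEAD")
  expect_identical(clamped_low$order, 1L)     # failure response only
  expect_identical(clamped_low$classes, "LAVO")
})

test_that("bifurcation diagrams merge branches and report overlap windows", {
  p90 <- params_at_pct(surr, 90)
  fp_short <- newton_shoot(surr, surr_attractor(90, "short")$state,
                           params = p90)
  br_short <- continue_branch(surr, fp_short, "pctGKr", c(10, 95),
                              initial_step = -4, max_points = 60,
                              stop_mult = 5)
  p30 <- params_at_pct(surr, 30)
  fp_lavo <- newton_shoot(surr, surr_attractor(30, "lavo")$state,
                          params = p30)
  br_lavo <- continue_branch(surr, fp_lavo, "pctGKr", c(10, 95),
                             initial_step = 4, max_points = 60,
                             stop_mult = 5)
  dg <- build_bifurcation_diagram(surr, list(br_short, br_lavo))
  expect_s3_class(dg, "bifurcation_diagram")
  expect_true(all(c("param", "stable", "branch") %in% names(dg$table)))
  w <- dg$multistable_windows
  expect_identical(nrow(w), 1L)
  # the overlap window spans a good part of the bistable range
  # (bounded below by the later of the two seeds' stable ends)
  expect_lte(w$lo, 30)
  expect_gt(w$hi, 80)
})
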