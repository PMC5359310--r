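test_that("sink-limited benchmark matches the closed-form solution", {
  p <- analytic_params(alpha2 = 0.34)
  init <- tree_state(0.1, 20, p$S1)
  fc <- constant_forcing(0:40)
  tr <- simulate_tree(init, p, fc, c(0, 40), mode = "sink_only")
  ref <- analytic_reference(init, p, times = tr$time)
  expect_lt(max(abs(tr$r - ref$r) / ref$r), 1e-6)
  expect_lt(max(abs(tr$h - ref$h) / ref$h), 1e-6)
  # radius grows linearly at k_lat / (1 + alpha2): 0.15 m over 10 y
  expect_equal(ref$r[ref$time == 10] - ref$r[ref$time == 0], 0.15,
               tolerance = 1e-9)
  # slope is independent of the starting radius
  ref2 <- analytic_reference(tree_state(0.05, 18, p$S1), p, times = 0:10)
  expect_equal(diff(ref2$r), diff(ref$r[1:11]))
  # validity guards fire outside the simplified configuration
  expect_error(analytic_reference(init, tree_params(), times = 0:300),
               "invalid")
  expect_error(analytic_reference(tree_state(2, 4, 0.2),
                                  tree_params(h2 = 1e8), times = 0:5),
               "apical")
})

test_that("adaptive and trapezoidal integrators agree", {
  p <- reference_params()
  init <- tree_state(0.08, 15)
  fc <- synth_forcing(48:188, seed = 11)
  cc <- cross_check(init, p, fc, c(48, 188), dt = 0.1)
  expect_lt(cc$max_rel_h_discrepancy, 1e-4)
  # halving the trapezoidal step shrinks its error roughly 4x (2nd order)
  fcc <- constant_forcing(0:30)
  p2 <- analytic_params()
  in2 <- tree_state(0.1, 20, p2$S1)
  ref <- analytic_reference(in2, p2, times = c(0, 30))
  err <- vapply(c(0.4, 0.2, 0.1), function(dt) {
    tp <- sinksource:::trapezoid_solve(in2, p2, fcc, c(0, 30), dt = dt,
                                       mode = "sink_only")
    abs(tp$h[nrow(tp)] - ref$h[2])
  }, 0)
  expect_gt(err[1] / err[2], 2.5)
  expect_gt(err[2] / err[3], 2.5)
  # against the closed form both methods are < 1e-6 off
  tr <- simulate_tree(in2, p2, fcc, c(0, 30), mode = "sink_only")
  expect_lt(abs(tr$h[nrow(tr)] - ref$h[2]) / ref$h[2], 1e-6)
  tp <- sinksource:::trapezoid_solve(in2, p2, fcc, c(0, 30), dt = 0.05,
                                     mode = "sink_only")
  expect_lt(abs(tp$h[nrow(tp)] - ref$h[2]) / ref$h[2], 1e-6)
})

test_that("carbon is conserved along trajectories", {
  p <- reference_params()
  fc <- synth_forcing(48:188, seed = 5)
  for (initial in list(tree_state(0.08, 15), tree_state(0.15, 22, 0.35))) {
    tr <- simulate_tree(initial, p, fc, c(48, 188), quiet = TRUE)
    aud <- mass_balance_audit(tr)
    # within 10x solver tolerance (rtol 1e-8) on the relative scale
    expect_lt(aud[["rel"]], 1e-7)
  }
})

test_that("constant alpha2 keeps the allometric power law invariant", {
  p <- reference_params(alpha2 = 0.41)
  fc <- synth_forcing(48:188, seed = 9)
  tr <- simulate_tree(tree_state(0.09, 16), p, fc, c(48, 188), quiet = TRUE)
  pred_h <- tr$h[1] * (tr$r / tr$r[1])^(2 * p$alpha2)
  expect_lt(max(abs(tr$h - pred_h) / tr$h), 1e-5)
})

test_that("height stays below the meristem limit h2", {
  p <- reference_params()
  fc <- synth_forcing(48:448, seed = 2)
  tr <- simulate_tree(tree_state(0.08, 15), p, fc, c(48, 448), quiet = TRUE)
  expect_true(all(tr$h < p$h2))
  expect_true(all(diff(tr$h) > -1e-9))
  # the reference stand arc: ~15 m at 48 y rising into the 30s by 188 y
  h188 <- tr$h[tr$time == 188]
  expect_gt(h188, 30); expect_lt(h188, p$h2)
})

test_that("storage never falls below its critical value", {
  p <- reference_params()
  fc <- synth_forcing(48:188, seed = 3)
  # start with excess storage under darkness: storage drains to S1, not past
  fc_dark <- fc; fc_dark$Q1 <- rep(0, nrow(fc))
  tr <- suppressWarnings(
    simulate_tree(tree_state(0.2, 22, 0.5), p, fc_dark, c(48, 80)))
  expect_true(all(tr$S >= p$S1 - 1e-9))
  expect_true(attr(tr, "stress"))
  expect_true(all(tr$growth[tr$S <= p$S1 + 1e-9] < 0))
})

test_that("zero PAR from the critical reserve gives stress, not growth", {
  p <- reference_params()
  fc <- constant_forcing(0:20, Q1 = 0)
  expect_warning(tr <- simulate_tree(tree_state(0.1, 15), p, fc, c(0, 20)),
                 "stress")
  expect_true(all(tr$growth < 0))
  expect_true(all(diff(tr$r) < 0))   # slow shrinkage, no collapse
  expect_true(all(tr$r > 0))
})

test_that("simulation is deterministic and validates its inputs", {
  p <- reference_params()
  fc <- synth_forcing(48:120, seed = 4)
  t1 <- simulate_tree(tree_state(0.08, 15), p, fc, c(48, 120), quiet = TRUE)
  t2 <- simulate_tree(tree_state(0.08, 15), p, fc, c(48, 120), quiet = TRUE)
  expect_identical(t1$r, t2$r)
  expect_identical(t1$h, t2$h)
  expect_identical(t1$S, t2$S)
  # forcing must cover the span
  expect_error(simulate_tree(tree_state(0.08, 15), p, fc, c(40, 120)),
               "cover")
  expect_error(simulate_tree(tree_state(0.08, 15), p, fc, c(48, 200)),
               "cover")
  # gappy forcing is rejected at construction
  expect_error(forcing_series(data.frame(year = c(1, 2, 4), T = 15,
                                         Q1 = 100, Cg = 300)), "gap")
})

test_that("reference trees are source-limited young, sink-limited mature", {
  p <- reference_params()
  fc <- synth_forcing(48:188, seed = 1)
  tr <- simulate_tree(tree_state(0.08, 15), p, fc, c(48, 188), quiet = TRUE)
  reg <- tr$regime[match(48:188, tr$time)]
  expect_identical(reg[1], "source")
  expect_identical(reg[length(reg)], "sink")
  # one forward switch, no flapping at annual resolution
  expect_equal(sum(diff(reg == "sink") == 1), 1)
})

test_that("red:far-red forcing drives alpha2 through the exponential law", {
  p <- reference_params(alpha0 = 0.8, alpha3 = 1.0)
  # constant Ra must be equivalent to the constant-alpha2 run it implies
  ra <- 0.75
  a2 <- alpha2_from_redfarred(ra, 0.8, 1.0)
  fc_ra <- synth_forcing(48:120, Ra = ra, seed = 6)
  fc_plain <- synth_forcing(48:120, seed = 6)
  tr_ra <- simulate_tree(tree_state(0.08, 15), p, fc_ra, c(48, 120),
                         quiet = TRUE)
  p_const <- reference_params(alpha2 = a2)
  tr_const <- simulate_tree(tree_state(0.08, 15), p_const, fc_plain,
                            c(48, 120), quiet = TRUE)
  expect_equal(tr_ra$h, tr_const$h, tolerance = 1e-10)
  expect_equal(unique(tr_ra$alpha2), a2)
  # stronger shading (lower Ra) shifts growth towards height
  fc_shade <- synth_forcing(48:120, Ra = 0.3, seed = 6)
  tr_shade <- simulate_tree(tree_state(0.08, 15), p, fc_shade, c(48, 120),
                            quiet = TRUE)
  expect_gt(tr_shade$alpha2[1], tr_ra$alpha2[1])
  expect_gt(tr_shade$h[50] / tr_shade$r[50], tr_ra$h[50] / tr_ra$r[50])
})

test_that("sink-off mode pins storage and frees growth from the cap", {
  p <- reference_params()
  fc <- synth_forcing(48:188, seed = 1)
  base <- simulate_tree(tree_state(0.08, 15), p, fc, c(48, 188),
                        quiet = TRUE)
  off <- simulate_tree(tree_state(0.08, 15), p, fc, c(48, 188),
                       mode = "sink_off", quiet = TRUE)
  expect_true(all(off$S == p$S1))
  expect_true(all(off$regime == "source"))
  expect_true(all(off$h - base$h >= -1e-9))
})
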