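test_that("allometric constant and height are mutual inverses", {
  expect_equal(allometry_gamma(1, 1, 0.57), 1)
  expect_equal(allometry_gamma(0.1, 10, 0.4), 63.09573, tolerance = 1e-6)
  expect_equal(allometric_height(0.2, 63.09573, 0.4), 17.41101,
               tolerance = 1e-6)
  # round trip for a grid of states
  for (a2 in c(0.34, 0.38, 0.43)) {
    for (r0 in c(0.05, 0.2, 0.8)) {
      g <- allometry_gamma(r0, 17, a2)
      expect_equal(allometric_height(r0, g, a2), 17)
    }
  }
  # doubling r multiplies h by 2^(2 alpha2)
  g <- allometry_gamma(0.1, 12, 0.4)
  expect_equal(allometric_height(0.2, g, 0.4) / allometric_height(0.1, g, 0.4),
               2^0.8)
  expect_error(allometry_gamma(-1, 10, 0.4), "positive")
  expect_error(allometric_height(0.1, -2, 0.4), "positive")
})

test_that("red:far-red control of the meristem activity ratio", {
  expect_equal(alpha2_from_redfarred(0, 0.6, 1.2), 0.6)
  # unshaded value at Ra = 1
  expect_equal(alpha2_from_redfarred(1, 0.6, 1.2), 0.6 * exp(-1.2))
  expect_equal(alpha2_from_redfarred(c(0, 2, 5), 0.5, 0), rep(0.5, 3))
  ra <- seq(0, 3, by = 0.25)
  expect_true(all(diff(alpha2_from_redfarred(ra, 0.6, 0.8)) < 0))
  expect_error(alpha2_from_redfarred(-0.1, 0.6, 1), ">= 0")
})

test_that("alpha2 is recoverable from two noiseless stand measurements", {
  est <- alpha2_from_allometry(c(h = 10, r = 0.1), c(h = 17.41101, r = 0.2))
  expect_equal(est$alpha2, 0.4, tolerance = 1e-6)
  expect_true(est$valid)
  # equal heights -> exponent zero, flagged invalid
  est0 <- alpha2_from_allometry(c(h = 10, r = 0.1), c(h = 10, r = 0.3))
  expect_equal(est0$alpha2, 0)
  expect_false(est0$valid)
  expect_error(alpha2_from_allometry(c(h = 10, r = 0.1), c(h = 12, r = 0.1)),
               "identical")
})

test_that("environmental factors have the right shape and bounds", {
  # asymmetric temperature parabola: optimum, roots, a hand value
  expect_equal(temperature_factor(18), 1)
  expect_equal(temperature_factor(39), 0)
  expect_equal(temperature_factor(-7), 0)
  expect_equal(temperature_factor(28.5), 0.75)
  expect_equal(temperature_factor(50), 0)   # clamped beyond the root
  # saturating CO2 and PAR factors
  expect_equal(co2_factor(0), 0)
  expect_equal(co2_factor(500, 500), 1 - exp(-1))
  expect_equal(par_factor(1e7, 1000), 1, tolerance = 1e-9)
  expect_true(all(diff(co2_factor(seq(0, 2000, 100))) > 0))
  # hydraulic factor: 1 at ground, 0.25 at h1, clamped root at h1/beta
  expect_equal(hydraulic_factor(0), 1)
  expect_equal(hydraulic_factor(90, 90, 0.75), 0.25)
  expect_equal(hydraulic_factor(120, 90, 0.75), 0)
  expect_equal(hydraulic_factor(150, 90, 0.75), 0)
  # all factors within [0, 1] over wide random inputs
  set.seed(1)
  Tg <- runif(200, -30, 60); hg <- runif(200, 0, 200)
  expect_true(all(temperature_factor(Tg) >= 0 & temperature_factor(Tg) <= 1))
  expect_true(all(hydraulic_factor(hg) >= 0 & hydraulic_factor(hg) <= 1))
})

test_that("assimilation is the factor product and behaves monotonically", {
  p <- tree_params()
  s <- st(0.2, 20)
  # all factors driven to ~1: A -> Amax * r^2 * h (pi folded into Amax)
  sat <- list(T = 18, Q1 = 1e9, Cg = 1e9)
  p_flat <- tree_params(beta_h1 = 67.5e9)  # push h1 out so fH ~ 1
  expect_equal(assimilation(s, sat, p_flat), 517.7345, tolerance = 1e-4)
  # any zero factor kills assimilation
  expect_equal(assimilation(s, list(T = 18, Q1 = 0, Cg = 400), p), 0)
  expect_equal(assimilation(s, list(T = 39, Q1 = 800, Cg = 400), p), 0)
  # product form against explicit re-evaluation on random inputs
  set.seed(42)
  for (i in 1:25) {
    s2 <- st(runif(1, 0.02, 1), runif(1, 1, 100))
    f <- list(T = runif(1, -5, 40), Q1 = runif(1, 0, 3000),
              Cg = runif(1, 100, 900))
    expected <- p$Amax * co2_factor(f$Cg, p$Cr) * par_factor(f$Q1, p$Qr) *
      temperature_factor(f$T, p$Topt, p$Ti_above, p$Ti_below) *
      hydraulic_factor(s2$h, p$h1, p$beta) * s2$r^2 * s2$h
    expect_equal(assimilation(s2, f, p), expected)
  }
  # increasing in Cg and Q1, maximal at Topt
  base <- list(T = 15, Q1 = 800, Cg = 300)
  a0 <- assimilation(s, base, p)
  expect_gt(assimilation(s, list(T = 15, Q1 = 800, Cg = 400), p), a0)
  expect_gt(assimilation(s, list(T = 15, Q1 = 900, Cg = 300), p), a0)
  expect_gt(assimilation(s, list(T = 18, Q1 = 800, Cg = 300), p), a0)
  # crown depth vs water potential: h * (h1 - beta h) peaks at h1/(2 beta)
  hpk <- p$h1 / (2 * p$beta)
  a_pk <- assimilation(st(0.2, hpk), base, p)
  expect_gt(a_pk, assimilation(st(0.2, hpk - 5), base, p))
  expect_gt(a_pk, assimilation(st(0.2, hpk + 5), base, p))
})

test_that("meristem volume and the sink cap", {
  expect_equal(meristem_volume(0.2, 20, 1), 25.2584, tolerance = 1e-5)
  # lateral term dominates for h >> r
  expect_equal(meristem_volume(0.1, 500, 1), 2 * pi * 0.1 * 500,
               tolerance = 1e-3)
  p <- tree_params(alpha2 = 0.34)
  expect_equal(sink_cap(st(0.2, 47), p), 0)     # at the limit height
  expect_equal(sink_cap(st(0.2, 60), p), 0)     # clamped above it
  expect_equal(sink_cap(st(0.2, 20), p), 106.4537, tolerance = 1e-5)
  # linear height factor: half the unlimited cap at h2/2 for equal Vme
  v <- meristem_volume(0.2, 23.5, 1)
  expect_equal(sink_cap(st(0.2, 23.5), p),
               p$g1 * p$k_lat * 0.5 * v)
  # strictly increasing in r at fixed h < h2
  caps <- vapply(seq(0.05, 0.5, by = 0.05),
                 function(r) sink_cap(st(r, 20), p), 0)
  expect_true(all(diff(caps) > 0))
})

test_that("parameter constructor validates and derives composites", {
  p <- tree_params()
  expect_equal(p$h1, 90)           # beta_h1 = 67.5, beta = 3/4
  expect_equal(p$C, 73 * pi)
  expect_equal(p$Amax, 206 * pi)
  expect_error(tree_params(g1 = -1), "positive")
  expect_error(tree_params(beta = 1.4), "beta")
  expect_error(tree_params(alpha0 = 0.5), "together")
  expect_warning(tree_params(alpha2 = 1.2), "plausible")
  # reference calibration stays inside the stated margins
  pr <- reference_params()
  expect_equal(pr$Amax_over_pi / 206, 1.2)
  expect_equal(pr$k_lat / 0.0201, 0.5)
  expect_true(pr$h2 / 47 >= 0.5 && pr$h2 / 47 <= 1.5)
})

test_that("parameter YAML config round-trips", {
  p <- reference_params(alpha2 = 0.41)
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  p2 <- read_params(f)
  for (nm in c("g1", "Amax_over_pi", "k_lat", "h2", "alpha2", "Qr", "Cr"))
    expect_equal(p2[[nm]], p[[nm]])
  # unknown keys are rejected
  writeLines("g1: 365\nbogus_key: 3", f)
  expect_error(read_params(f), "bogus_key")
})

test_that("tree state validates and derives carbon pools", {
  expect_error(tree_state(-0.1, 10), "positive")
  expect_error(tree_state(0.1, 0), "positive")
  expect_error(tree_state(0.1, 10, -0.5), "non-negative")
  p <- tree_params()
  pools <- carbon_pools(st(0.2, 20, 0.2), p)
  expect_equal(unname(pools["Mc"]), 365 * pi * 0.04 * 20)
  expect_equal(unname(pools["Sc0"]), 0)   # S at the critical value
  expect_equal(unname(pools["Mtot"]), unname(pools["Mc"]))
  pools2 <- carbon_pools(st(0.2, 20, 0.5), p)
  expect_gt(pools2[["Sc0"]], 0)
})
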