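test_that("r_squared matches hand computation and is affine-invariant", {
  expect_equal(r_squared(c(10, 20, 30), c(10, 20, 30)), 1)
  expect_equal(r_squared(rep(20, 3), c(10, 20, 30)), 0)
  expect_equal(r_squared(c(12, 19, 31), c(10, 20, 30)), 1 - 6 / 200)
  obs <- c(14.2, 18.9, 25.0, 31.3); pred <- c(15, 18, 26, 30.5)
  expect_equal(r_squared(pred * 3.28 + 2, obs * 3.28 + 2),
               r_squared(pred, obs))
  expect_error(r_squared(c(1, 2), c(5, 5)), "variance")
  expect_error(r_squared(1, 2), "at least 2")
})

test_that("measurement series validation reports the problem", {
  expect_error(measurement_series(data.frame(age = 1:3)), "height")
  expect_error(measurement_series(data.frame(age = c(2, 1, 3),
                                             height = c(5, 6, 7))),
               "increasing")
  expect_error(measurement_series(data.frame(age = 1:2,
                                             height = c(3, -1))),
               "positive")
  m <- measurement_series(data.frame(age = c(48, 60), height = c(15, 17),
                                     density = c(3500, 2000)))
  expect_s3_class(m, "measurement_series")
})

test_that("zero free parameters returns the reference misfit unchanged", {
  p <- reference_params()
  fc <- synth_forcing(48:120, seed = 21)
  stand <- synth_stand(stand_scenario(end_age = 120, params = p, seed = 21),
                       fc)
  ft <- fit_tree(stand$measurements, fc, params0 = p,
                 spec = fit_spec(free = character(0)))
  expect_length(coef(ft), 0)
  for (nm in c("Amax_over_pi", "k_lat", "h2"))
    expect_equal(ft$params[[nm]], p[[nm]])
  expect_gt(ft$r_squared, 0.9)   # truth parameters, noise only
})

test_that("noiseless synthetic series recovers perturbed parameters", {
  p0 <- reference_params()
  truth <- reference_params(k_lat = p0$k_lat * 1.12, h2 = p0$h2 * 0.93)
  fc <- synth_forcing(48:188, seed = 31)
  stand <- synth_stand(stand_scenario(obs_noise_sd = 0, params = truth,
                                      seed = 31), fc)
  ft <- fit_tree(stand$measurements, fc, params0 = p0,
                 spec = fit_spec(free = c("k_lat", "h2")),
                 alpha2 = truth$alpha2)
  expect_lt(abs(coef(ft)[["k_lat"]] - truth$k_lat) / truth$k_lat, 0.01)
  expect_lt(abs(coef(ft)[["h2"]] - truth$h2) / truth$h2, 0.01)
  expect_lt(ft$ssr, 1e-3)
  expect_true(ft$convergence$converged)
})

test_that("noisy fits stay in their boxes with high R^2", {
  p0 <- reference_params()
  fc <- synth_forcing(48:188, seed = 41)
  stand <- synth_stand(stand_scenario(obs_noise_sd = 0.5, params = p0,
                                      seed = 41), fc)
  spec <- fit_spec()
  ft <- fit_tree(stand$measurements, fc, params0 = p0, spec = spec)
  expect_gt(ft$r_squared, 0.95)
  mult <- ft$multipliers
  expect_true(all(mult >= 1 - spec$rel_bounds - 1e-9))
  expect_true(all(mult <= 1 + spec$rel_bounds + 1e-9))
})

test_that("enlarging the bound box never worsens the minimized loss", {
  p0 <- reference_params()
  truth <- reference_params(k_lat = p0$k_lat * 1.3)  # outside a 20% box
  fc <- synth_forcing(48:150, seed = 51)
  stand <- synth_stand(stand_scenario(end_age = 150, obs_noise_sd = 0,
                                      params = truth, seed = 51), fc)
  ft_narrow <- fit_tree(stand$measurements, fc, params0 = p0,
                        spec = fit_spec(free = "k_lat", rel_bound = 0.2,
                                        wide = NULL),
                        alpha2 = truth$alpha2)
  ft_wide <- fit_tree(stand$measurements, fc, params0 = p0,
                      spec = fit_spec(free = "k_lat", rel_bound = 0.5,
                                      wide = NULL),
                      alpha2 = truth$alpha2)
  expect_lte(ft_wide$ssr, ft_narrow$ssr + 1e-10)
  # the narrow fit is pinned at its upper bound
  expect_equal(unname(ft_narrow$multipliers), 1.2, tolerance = 1e-6)
})

test_that("h2 site transfer refit recovers a shifted limit height", {
  p0 <- reference_params()
  fc <- synth_forcing(48:188, seed = 61)
  stand1 <- synth_stand(stand_scenario(params = p0, seed = 61), fc)
  ft1 <- fit_tree(stand1$measurements, fc, params0 = p0,
                  spec = fit_spec(free = c("Amax_over_pi", "k_lat")))
  # second site: same physiology but h2 shifted +10%
  truth2 <- ft1$params
  truth2 <- reference_params(h2 = ft1$params$h2 * 1.1,
                             Amax_over_pi = ft1$params$Amax_over_pi,
                             k_lat = ft1$params$k_lat)
  stand2 <- synth_stand(stand_scenario(obs_noise_sd = 0, params = truth2,
                                       seed = 62), fc)
  ft2 <- refit_h2(ft1, stand2$measurements, fc, margin = 0.2)
  expect_lt(abs(ft2$params$h2 - truth2$h2) / truth2$h2, 0.02)
  # nothing but h2 may change
  for (nm in c("Amax_over_pi", "k_lat", "C_over_pi", "g1", "Qr"))
    expect_equal(ft2$params[[nm]], ft1$params[[nm]])
  # margin 0 returns the calibration untouched
  expect_identical(refit_h2(ft1, stand2$measurements, fc, margin = 0), ft1)
})

test_that("the optional joint height+volume loss fits cleanly", {
  fc <- synth_forcing(48:120, seed = 81)
  stand <- synth_stand(stand_scenario(end_age = 120, seed = 81), fc)
  ft <- fit_tree(stand$measurements, fc, params0 = reference_params(),
                 spec = fit_spec(free = "k_lat", loss = "height_volume"))
  expect_gt(ft$r_squared, 0.9)
  expect_true(ft$convergence$converged)
})

test_that("stand prediction reports heights and cylinder volumes", {
  p <- reference_params()
  fc <- synth_forcing(48:120, seed = 71)
  pr <- predict_stand(p, fc, c(0.08, 15), c(48, 70, 100, 120))
  expect_equal(nrow(pr), 4)
  expect_true(all(diff(pr$height) > 0))
  expect_equal(pr$volume, pi * pr$radius^2 * pr$height)
  # cylinder volume spot value
  expect_equal(pi * 0.2^2 * 20, 2.513274, tolerance = 1e-6)
  # self-prediction of a noiseless stand is near-perfect
  stand <- synth_stand(stand_scenario(end_age = 120, obs_noise_sd = 0,
                                      params = p, seed = 71), fc)
  m <- stand$measurements
  pr2 <- predict_stand(p, fc, c(m$radius[1], m$height[1]), m$age)
  expect_gt(r_squared(pr2$height, m$height), 0.999)
})
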