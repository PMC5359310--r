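# Synthetic forcing and stand generators.
#
# The real long-term beech stand records this model was designed around
# (planted stands measured from age 48 y in A.D. 1870 to 188 y in A.D.
# 2010, at irregular intervals of 8 +/- 3 y, mean height of the 100
# largest-diameter trees rising from roughly 15 m towards 35 m) are not
# distributed with any public archive, so simulation studies here run on
# synthetic stands with the same sampling structure, generated from the
# model itself plus an explicit observation-noise model.

#' Generate a synthetic annual forcing series
#'
#' Annual mean growing-season temperature is drawn around a site
#' climatology; PAR is constant or linearly trended; CO2 follows either a
#' constant level or a monotone historical-style ramp (roughly the
#' industrial-era rise: ~288 ppm at the start of the 1870s record to ~390
#' ppm by 2010, interpolated exponentially in between).
#'
#' @param years integer vector of ages (or calendar years), consecutive.
#' @param T_mean,T_sd climatology mean and interannual sd of temperature
#'   (degrees C). \code{T_sd = 0} gives a constant series.
#' @param par_level mean PAR (W/m^2).
#' @param par_trend additive linear PAR trend over the whole span (W/m^2).
#' @param co2 \code{"ramp"} for the historical-style rise or
#'   \code{"constant"} for a flat series at \code{co2_start}.
#' @param co2_start,co2_end CO2 mixing ratios anchoring the ramp (ppm).
#' @param Ra optional constant red:far-red ratio; if non-NULL an \code{Ra}
#'   column is added.
#' @param seed integer seed fixing the temperature draws.
#' @return A [forcing_series()].
#' @export
#' @examples
#' fc <- synth_forcing(48:188, seed = 42)
#' range(fc$Cg)   # ~288 to ~390 ppm
synth_forcing <- function(years, T_mean = 15, T_sd = 0.8,
                          par_level = 1200, par_trend = 0,
                          co2 = c("ramp", "constant"),
                          co2_start = 288, co2_end = 390,
                          Ra = NULL, seed = 1) {
  co2 <- match.arg(co2)
  if (!length(years)) stop("years must be non-empty", call. = FALSE)
  n <- length(years)
  set.seed(seed)
  T_C <- T_mean + stats::rnorm(n, 0, T_sd)
  Q1 <- par_level + par_trend * seq(0, 1, length.out = n)
  frac <- if (n > 1) seq(0, 1, length.out = n) else 0
  Cg <- switch(co2,
               ramp = co2_start * (co2_end / co2_start)^(frac^2),
               constant = rep(co2_start, n))
  out <- data.frame(year = years, T = T_C, Q1 = Q1, Cg = Cg)
  if (!is.null(Ra)) out$Ra <- rep(Ra, n)
  forcing_series(out)
}

#' Stand scenario: sampling design of a synthetic measurement series
#'
#' Mirrors the long-term yield-experiment protocol: observations from
#' \code{start_age} to \code{end_age} at irregular intervals of mean 8 and
#' sd 3 years, with additive Gaussian noise on the measured heights (and
#' radii, when emitted).
#'
#' @param start_age,end_age first and last measured age (y).
#' @param interval_mean,interval_sd mean and sd of the measurement
#'   interval (y); intervals are clipped at 2 y.
#' @param obs_noise_sd observation noise sd on height (m).
#' @param r0,h0 initial radius and height (m) at \code{start_age}.
#' @param params true model parameters ([tree_params()]).
#' @param seed integer seed.
#' @return A list of class \code{"stand_scenario"}.
#' @export
stand_scenario <- function(start_age = 48, end_age = 188,
                           interval_mean = 8, interval_sd = 3,
                           obs_noise_sd = 0.5, r0 = 0.08, h0 = 15,
                           params = reference_params(), seed = 1) {
  stopifnot(start_age < end_age, interval_mean > 0, obs_noise_sd >= 0)
  structure(list(start_age = start_age, end_age = end_age,
                 interval_mean = interval_mean, interval_sd = interval_sd,
                 obs_noise_sd = obs_noise_sd, r0 = r0, h0 = h0,
                 params = params, seed = seed),
            class = "stand_scenario")
}

#' Generate a synthetic stand measurement series
#'
#' Simulates the true trajectory from the scenario's initial state and
#' parameters, draws irregular measurement ages, and adds independent
#' Gaussian observation noise to heights and radii. The noiseless truth is
#' returned alongside for test assertions; the first observation is kept
#' noise-free so that it can serve as the (r0, h0) initial condition, as in
#' the stand protocol.
#'
#' @param scenario a [stand_scenario()].
#' @param forcing a [forcing_series()] covering the scenario ages.
#' @return A list with \code{measurements} (data frame: age, height,
#'   radius), \code{truth} (noiseless data frame at the same ages),
#'   \code{trajectory} (the full annual truth) and \code{scenario}.
#' @export
#' @examples
#' sc <- stand_scenario(seed = 7)
#' st <- synth_stand(sc, synth_forcing(48:188, seed = 7))
#' nrow(st$measurements)   # ~17-18 ages between 48 and 188
synth_stand <- function(scenario, forcing) {
  stopifnot(inherits(scenario, "stand_scenario"))
  set.seed(scenario$seed)
  ages <- scenario$start_age
  repeat {
    step <- max(2, stats::rnorm(1, scenario$interval_mean,
                                scenario$interval_sd))
    nxt <- ages[length(ages)] + step
    if (nxt >= scenario$end_age) break
    ages <- c(ages, nxt)
  }
  ages <- unique(round(c(ages, scenario$end_age), 1))
  init <- tree_state(scenario$r0, scenario$h0, scenario$params$S1)
  traj <- simulate_tree(init, scenario$params, forcing,
                        c(scenario$start_age, scenario$end_age),
                        times = sort(unique(c(
                          seq(scenario$start_age, scenario$end_age), ages))),
                        quiet = TRUE)
  idx <- match(ages, traj$time)
  truth <- data.frame(age = ages, height = traj$h[idx], radius = traj$r[idx])
  noise_h <- stats::rnorm(length(ages), 0, scenario$obs_noise_sd)
  noise_r <- stats::rnorm(length(ages), 0, scenario$obs_noise_sd / 100)
  noise_h[1] <- 0; noise_r[1] <- 0   # first record anchors (r0, h0)
  meas <- data.frame(age = ages,
                     height = truth$height + noise_h,
                     radius = pmax(truth$radius + noise_r, 1e-4))
  list(measurements = measurement_series(meas), truth = truth,
       trajectory = traj, scenario = scenario)
}

#' Generate a trio of synthetic stands sharing one forcing
#'
#' Emulates a three-stand site: the stands sit next to each other (one
#' shared environmental forcing, one shared physiological parameter set)
#' but differ in initial size and in their allometric exponent (alpha2,
#' within the plausible 0.34-0.43 range), reflecting different thinning
#' histories. Supports the fit-on-stand-1 / predict-stands-2-and-3
#' workflow.
#'
#' @param params shared true physiological parameters.
#' @param forcing shared [forcing_series()]; generated from
#'   \code{seeds[1]} if NULL.
#' @param initials list of three \code{c(r0, h0)} pairs.
#' @param alpha2 numeric length 3, per-stand meristem activity ratios.
#' @param obs_noise_sd observation noise sd (m).
#' @param start_age,end_age measurement span (y).
#' @param seeds integer length 3, per-stand noise/sampling seeds.
#' @return List of three [synth_stand()] results plus the shared
#'   \code{forcing}.
#' @export
synth_stand_trio <- function(params = reference_params(), forcing = NULL,
                             initials = list(c(0.080, 15), c(0.072, 14),
                                             c(0.088, 16)),
                             alpha2 = c(0.38, 0.36, 0.40),
                             obs_noise_sd = 0.5,
                             start_age = 48, end_age = 188,
                             seeds = c(101, 102, 103)) {
  stopifnot(length(initials) == 3, length(alpha2) == 3, length(seeds) == 3)
  if (is.null(forcing))
    forcing <- synth_forcing(seq(start_age, end_age), seed = seeds[1])
  stands <- vector("list", 3)
  for (i in 1:3) {
    p <- params
    p$alpha2 <- alpha2[i]
    sc <- stand_scenario(start_age = start_age, end_age = end_age,
                         obs_noise_sd = obs_noise_sd,
                         r0 = initials[[i]][1], h0 = initials[[i]][2],
                         params = p, seed = seeds[i])
    stands[[i]] <- synth_stand(sc, forcing)
  }
  list(stands = stands, forcing = forcing, params = params,
       alpha2 = alpha2)
}
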