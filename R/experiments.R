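# Scripted numerical experiments: consistency checks, sensitivity fans,
# regime maps, sink-off comparisons, CO2 counterfactuals. All deterministic
# given their inputs.

#' Maximal annual radial increment implied by the parameters
#'
#' The asymptotic sink-limited radial growth rate of a tall tree: with the
#' lateral meristem dominant (2*pi*r*h >> pi*r^2/t_ratio), storage at its
#' critical value and no water-potential limitation ((h2 - h)/h2 ~ 1), the
#' radius equation reduces to \code{dr/dt = k_lat / (1 + alpha2)},
#' independent of tree size. With the reference \code{k_lat = 0.0201} m/y
#' and \code{alpha2 = 0.34} this is 0.015 m/y, i.e. a maximal ring width of
#' 1.5 cm/y.
#'
#' @param params a [tree_params()].
#' @return Radial increment, m/y.
#' @export
#' @examples
#' max_radial_increment(tree_params(alpha2 = 0.34)) * 100  # cm/y
max_radial_increment <- function(params) {
  params$k_lat / (1 + params$alpha2)
}

#' Initial-condition sensitivity fan
#'
#' Re-simulates a stand under a grid of relative errors on the initial
#' radius and height. In the default \code{allometry = "independent"} mode
#' the two initial coordinates are perturbed independently (each member's
#' allometric constant follows from its own perturbed pair). In
#' \code{"from_base"} mode the initial height is derived from the
#' unperturbed stand's allometric constant evaluated at the perturbed
#' radius (then shifted by the h0 error) — the design used when the
#' stand's own height record is distrusted and its allometry is borrowed
#' from the reference stand.
#'
#' @param initial base [tree_state()] (or \code{c(r0, h0)}).
#' @param params a [tree_params()].
#' @param forcing a [forcing_series()].
#' @param t_span simulation span (y).
#' @param r0_errors relative errors on r0 (default -20\% to +20\% in 4\%
#'   steps).
#' @param h0_errors relative errors on h0 (default 0).
#' @param allometry see Description.
#' @param ... passed to [simulate_tree()].
#' @return A data frame (one row per member per output age) with columns
#'   \code{r0_error}, \code{h0_error}, \code{time}, \code{r}, \code{h},
#'   plus attribute \code{base} (the unperturbed trajectory).
#' @export
sensitivity_fan <- function(initial, params, forcing, t_span,
                            r0_errors = seq(-0.2, 0.2, by = 0.04),
                            h0_errors = 0,
                            allometry = c("independent", "from_base"),
                            ...) {
  allometry <- match.arg(allometry)
  if (!inherits(initial, "tree_state"))
    initial <- tree_state(initial[1], initial[2], params$S1)
  base_gamma <- allometry_gamma(initial$r, initial$h, params$alpha2)
  grid <- expand.grid(r0_error = r0_errors, h0_error = h0_errors)
  out <- vector("list", nrow(grid))
  base <- NULL
  for (i in seq_len(nrow(grid))) {
    r0 <- initial$r * (1 + grid$r0_error[i])
    h0 <- if (allometry == "from_base") {
      allometric_height(r0, base_gamma, params$alpha2) *
        (1 + grid$h0_error[i])
    } else {
      initial$h * (1 + grid$h0_error[i])
    }
    tr <- simulate_tree(tree_state(r0, h0, params$S1), params, forcing,
                        t_span, quiet = TRUE, ...)
    if (grid$r0_error[i] == 0 && grid$h0_error[i] == 0) base <- tr
    out[[i]] <- data.frame(r0_error = grid$r0_error[i],
                           h0_error = grid$h0_error[i],
                           time = tr$time, r = tr$r, h = tr$h)
  }
  structure(do.call(rbind, out), base = base)
}

#' Map of the limiting growth process over assimilation capacity and age
#'
#' Sweeps a grid of multipliers of the maximal assimilation parameter Amax
#' (normalised to 1 at its reference value), simulates each, and records
#' per-age height and the limiting process. Within each year the regime is
#' the time-majority of sub-annual right-hand-side classifications.
#'
#' @param params reference [tree_params()].
#' @param forcing [forcing_series()] covering the ages.
#' @param initial starting [tree_state()] (or \code{c(r0, h0)}).
#' @param amax_mult multipliers of the reference Amax.
#' @param ages integer ages to report (first = starting age).
#' @param dt_regime sub-annual sampling step for the regime majority (y).
#' @param ... passed to [simulate_tree()].
#' @return A list of class \code{"regime_map"}: \code{amax_mult},
#'   \code{ages}, matrices \code{height} and \code{regime}
#'   (multipliers x ages; regime entries "sink"/"source").
#' @export
regime_map <- function(params, forcing, initial,
                       amax_mult = seq(0.4, 2, by = 0.2),
                       ages = 48:188, dt_regime = 0.25, ...) {
  if (!inherits(initial, "tree_state"))
    initial <- tree_state(initial[1], initial[2], params$S1)
  t_span <- range(ages)
  hmat <- matrix(NA_real_, length(amax_mult), length(ages),
                 dimnames = list(amax_mult, ages))
  rmat <- matrix(NA_character_, length(amax_mult), length(ages),
                 dimnames = list(amax_mult, ages))
  for (i in seq_along(amax_mult)) {
    p <- params
    p$Amax_over_pi <- params$Amax_over_pi * amax_mult[i]
    p$Amax <- p$Amax_over_pi * pi
    tr <- simulate_tree(initial, p, forcing, t_span, dt_out = dt_regime,
                        quiet = TRUE, ...)
    is_int <- abs(tr$time - round(tr$time)) < 1e-9
    hmat[i, ] <- tr$h[is_int][match(ages, round(tr$time[is_int]))]
    yr <- floor(tr$time)
    yr[tr$time == t_span[2]] <- t_span[2] - 1   # last instant joins last year
    sink_share <- tapply(tr$regime == "sink", yr, mean)
    per_year <- ifelse(sink_share > 0.5, "sink", "source")
    # report the regime of the year starting at each age (last age: the
    # year ending there)
    idx <- match(pmin(ages, t_span[2] - 1), as.numeric(names(per_year)))
    rmat[i, ] <- per_year[idx]
  }
  structure(list(amax_mult = amax_mult, ages = ages, height = hmat,
                 regime = rmat),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat(sprintf("Regime map: %d Amax multipliers (%.2g-%.2g) x %d ages (%d-%d)\n",
              length(x$amax_mult), min(x$amax_mult), max(x$amax_mult),
              length(x$ages), min(x$ages), max(x$ages)))
  ta <- transition_age(x)
  for (i in seq_along(x$amax_mult))
    cat(sprintf("  Amax x %.2f: source->sink at age %s, final h %.1f m\n",
                x$amax_mult[i],
                ifelse(is.na(ta[i]), "never", ta[i]),
                x$height[i, ncol(x$height)]))
  invisible(x)
}

#' Age of the source-to-sink transition per Amax multiplier
#'
#' First reported age at which the regime is sink-limited and stays
#' sink-limited for the rest of the map row (NA if the row never settles
#' into sink limitation).
#'
#' @param map a [regime_map()].
#' @return Numeric vector along the map's multipliers.
#' @export
transition_age <- function(map) {
  vapply(seq_along(map$amax_mult), function(i) {
    sink <- map$regime[i, ] == "sink"
    if (!any(sink)) return(NA_real_)
    # last run of sink-limited years reaching the end
    j <- length(sink)
    if (!sink[j]) return(NA_real_)
    while (j > 1 && sink[j - 1]) j <- j - 1
    map$ages[j]
  }, 0)
}

#' Height gain from switching off the sink limit
#'
#' Re-runs every row of a regime-map sweep with the meristem cap removed
#' (growth always supply-limited, storage pinned at S1) and returns the
#' height difference (sink-off minus baseline). The difference is zero
#' wherever the baseline is source-limited (the cap is inactive there) and
#' grows large at high assimilation and late ages.
#'
#' @inheritParams regime_map
#' @return A list: \code{amax_mult}, \code{ages}, \code{height_diff}
#'   (matrix, m), \code{baseline} (the [regime_map()]), \code{height_off}.
#' @export
sink_off_comparison <- function(params, forcing, initial,
                                amax_mult = seq(0.4, 2, by = 0.2),
                                ages = 48:188, ...) {
  base <- regime_map(params, forcing, initial, amax_mult, ages, ...)
  if (!inherits(initial, "tree_state"))
    initial <- tree_state(initial[1], initial[2], params$S1)
  hoff <- matrix(NA_real_, length(amax_mult), length(ages),
                 dimnames = dimnames(base$height))
  for (i in seq_along(amax_mult)) {
    p <- params
    p$Amax_over_pi <- params$Amax_over_pi * amax_mult[i]
    p$Amax <- p$Amax_over_pi * pi
    tr <- simulate_tree(initial, p, forcing, range(ages),
                        mode = "sink_off", quiet = TRUE, ...)
    hoff[i, ] <- tr$h[match(ages, tr$time)]
  }
  list(amax_mult = amax_mult, ages = ages,
       height_diff = hoff - base$height, baseline = base,
       height_off = hoff)
}

#' CO2 counterfactual: historical ramp vs constant pre-industrial level
#'
#' Runs the model twice under forcing that differs only in CO2: the actual
#' (ramped) series vs the series held constant at its first-year value.
#' The constant arm grows more slowly whenever growth is source-limited,
#' quantifying the bias of ignoring the CO2 rise.
#'
#' @param params a [tree_params()].
#' @param forcing a [forcing_series()] whose \code{Cg} column carries the
#'   actual (e.g. ramped) CO2 series.
#' @param initial starting [tree_state()] (or \code{c(r0, h0)}).
#' @param t_span simulation span (y).
#' @param ... passed to [simulate_tree()].
#' @return List with trajectories \code{ramp} and \code{constant}, and a
#'   data frame \code{difference} (age, height difference ramp - constant).
#' @export
co2_counterfactual <- function(params, forcing, initial, t_span, ...) {
  if (!inherits(initial, "tree_state"))
    initial <- tree_state(initial[1], initial[2], params$S1)
  if (!inherits(forcing, "forcing_series")) forcing <- forcing_series(forcing)
  fc_const <- forcing
  fc_const$Cg <- rep(forcing$Cg[1], nrow(forcing))
  tr_ramp <- simulate_tree(initial, params, forcing, t_span, quiet = TRUE,
                           ...)
  tr_const <- simulate_tree(initial, params, fc_const, t_span,
                            quiet = TRUE, ...)
  ages <- intersect(tr_ramp$time, tr_const$time)
  list(ramp = tr_ramp, constant = tr_const,
       difference = data.frame(
         age = ages,
         height_diff = tr_ramp$h[match(ages, tr_ramp$time)] -
           tr_const$h[match(ages, tr_const$time)]))
}

#' Parameter recovery simulation study
#'
#' Generates many synthetic stands with known (jittered) parameters, fits
#' each with [fit_tree()], and reports per-parameter relative recovery
#' errors. The default design frees the source capacity (Amax) and the
#' meristem growth composite (k_lat) — the two rate parameters that are
#' separately identifiable from a height series, one governing each growth
#' regime — jitters the truth uniformly within +/-10\% of the reference,
#' observes heights with 0.5 m Gaussian noise, and starts the optimiser at
#' the reference values. (Freeing k_lat and h2 jointly is a near-collinear
#' design: over the sink-limited phase a larger k_lat with a smaller h2
#' yields almost the same heights; see the methods vignette.)
#'
#' @param n_stands number of synthetic stands.
#' @param free free parameter names (fitted and jittered).
#' @param truth_jitter relative half-width of the uniform truth jitter.
#' @param obs_noise_sd observation noise sd (m); 0 for noiseless recovery.
#' @param params0 reference parameters.
#' @param seed master seed (stand i uses seed + i).
#' @param ... passed to [fit_tree()] (e.g. \code{control}).
#' @return A list: \code{errors} (matrix n_stands x free, relative errors),
#'   \code{median_abs_rel_error} (per parameter), \code{truths},
#'   \code{estimates}.
#' @export
recovery_study <- function(n_stands = 20,
                           free = c("Amax_over_pi", "k_lat"),
                           truth_jitter = 0.1, obs_noise_sd = 0.5,
                           params0 = reference_params(), seed = 2024, ...) {
  est <- tru <- matrix(NA_real_, n_stands, length(free),
                       dimnames = list(NULL, free))
  spec <- fit_spec(free = free)
  for (i in seq_len(n_stands)) {
    set.seed(seed + i)
    mult <- stats::runif(length(free), 1 - truth_jitter, 1 + truth_jitter)
    truth <- set_free_params(params0, free,
                             vapply(free, function(nm) params0[[nm]], 0) *
                               mult)
    fc <- synth_forcing(48:188, seed = seed + i)
    st <- synth_stand(stand_scenario(obs_noise_sd = obs_noise_sd,
                                     params = truth, seed = seed + i), fc)
    ft <- fit_tree(st$measurements, fc, params0 = params0, spec = spec,
                   alpha2 = truth$alpha2, ...)
    tru[i, ] <- vapply(free, function(nm) truth[[nm]], 0)
    est[i, ] <- ft$estimate[free]
  }
  err <- (est - tru) / tru
  list(errors = err,
       median_abs_rel_error = apply(abs(err), 2, stats::median),
       truths = tru, estimates = est)
}
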