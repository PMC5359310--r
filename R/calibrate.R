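#' Validate a stand measurement series
#'
#' A measurement series holds mean tree age (y), mean height (m) and
#' optionally mean stem radius (m) and stand density (trees/ha, carried as
#' metadata only) at irregular ages. The first record supplies the initial
#' condition (r0, h0) for simulations.
#'
#' @param x data frame with columns \code{age}, \code{height} and
#'   optionally \code{radius}, \code{density}.
#' @param site,stand optional labels stored as attributes.
#' @return The validated data frame with class \code{"measurement_series"}.
#' @export
measurement_series <- function(x, site = NULL, stand = NULL) {
  x <- as.data.frame(x)
  if (!all(c("age", "height") %in% names(x)))
    stop("measurements need columns 'age' and 'height'", call. = FALSE)
  for (nm in intersect(c("age", "height", "radius", "density"), names(x))) {
    if (!is.numeric(x[[nm]]))
      stop("measurement column '", nm, "' is not numeric", call. = FALSE)
  }
  if (is.unsorted(x$age, strictly = TRUE))
    stop("measurement ages must be strictly increasing", call. = FALSE)
  if (any(x$height <= 0)) stop("heights must be positive", call. = FALSE)
  if ("radius" %in% names(x) && any(x$radius <= 0))
    stop("radii must be positive", call. = FALSE)
  structure(x, class = c("measurement_series", "data.frame"),
            site = site, stand = stand)
}

#' Specification of a bounded least-squares fit
#'
#' Declares which parameters are free and the relative box bounds around
#' their reference values. The default free set covers the physiological
#' constants with a +/-20\% box, widened to +/-50\% for the
#' coarsely-estimated meristem growth composite \code{k_lat} and for the
#' meristem limit height \code{h2} (whose site water potential is
#' uncertain). The meristem activity ratio alpha2 is not fitted: it is
#' fixed from the stand's own allometry.
#'
#' @param free character vector of free parameter names (arguments of
#'   [tree_params()]).
#' @param rel_bound default relative half-width of the box.
#' @param wide named numeric vector of per-parameter overrides of
#'   \code{rel_bound}.
#' @param loss \code{"height"} (default: sum of squared height errors) or
#'   \code{"height_volume"} (heights plus stem volumes, the latter rescaled
#'   to the height scale).
#' @return A list of class \code{"fit_spec"}.
#' @export
fit_spec <- function(free = c("Amax_over_pi", "C_over_pi", "C2_over_pi",
                              "k_lat", "h2", "Qr", "Cr", "S1", "g1"),
                     rel_bound = 0.2,
                     wide = c(k_lat = 0.5, h2 = 0.5),
                     loss = c("height", "height_volume")) {
  loss <- match.arg(loss)
  ok <- names(formals(tree_params))
  bad <- setdiff(free, ok)
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bounds <- stats::setNames(rep(rel_bound, length(free)), free)
  for (nm in intersect(names(wide), free)) bounds[nm] <- wide[[nm]]
  if (any(bounds <= 0) && length(free))
    stop("relative bounds must be positive", call. = FALSE)
  structure(list(free = free, rel_bounds = bounds, loss = loss),
            class = "fit_spec")
}

# replace free entries of a tree_params with values in `theta` (natural units)
set_free_params <- function(params0, free, theta) {
  args <- params0[intersect(names(formals(tree_params)), names(params0))]
  args <- args[!vapply(args, is.null, logical(1))]
  for (i in seq_along(free)) args[[free[i]]] <- theta[i]
  do.call(tree_params, args)
}

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot} with the total sum of squares taken about the
#' observation mean. Computed on the measurement ages only.
#'
#' @param predicted,observed equal-length numeric vectors (>= 2 values).
#' @return R^2 (<= 1; negative when the model does worse than the mean).
#' @export
#' @examples
#' r_squared(c(12, 19, 31), c(10, 20, 30))   # 0.97
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2)
    stop("need two equal-length series of at least 2 values", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observations have zero variance: R^2 undefined", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit model parameters to a stand height series
#'
#' Bounded nonlinear least squares: minimises the sum of squared
#' differences between simulated and observed heights at the measurement
#' ages, over a box of parameters centred on their reference values
#' (Levenberg-Marquardt with box constraints; parameters are rescaled to
#' their reference values so the optimiser works on dimensionless
#' multipliers). The fit is deterministic from the reference start point;
#' optional multi-start adds seeded jitter inside the box.
#'
#' The initial state is taken from the first measurement record. The
#' meristem activity ratio alpha2 is fixed: supplied explicitly, or
#' estimated from the stand's own first/last (height, radius) pair when
#' radii are present, else the reference value.
#'
#' @param measurements a [measurement_series()] (>= 3 records; the first
#'   must carry a radius unless \code{r0} is given).
#' @param forcing a [forcing_series()] covering the measured ages.
#' @param params0 reference parameters (box centres and start point).
#' @param spec a [fit_spec()].
#' @param alpha2 fixed meristem activity ratio; NULL to estimate from the
#'   stand allometry (requires radii).
#' @param r0 initial radius override (m), when measurements lack radii.
#' @param n_starts number of optimiser starts (1 = deterministic start at
#'   the reference values).
#' @param seed seed for the jittered extra starts (ignored when
#'   \code{n_starts = 1}).
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @param ... solver options passed on to [simulate_tree()] (e.g.
#'   \code{rtol}).
#' @return An object of class \code{"tree_fit"}; see
#'   [coef.tree_fit()], [predict.tree_fit()], [summary.tree_fit()].
#' @export
#' @examples
#' \donttest{
#' fc <- synth_forcing(48:188, seed = 3)
#' st <- synth_stand(stand_scenario(seed = 3), fc)
#' ft <- fit_tree(st$measurements, fc, spec = fit_spec(free = "k_lat"))
#' coef(ft); summary(ft)
#' }
fit_tree <- function(measurements, forcing, params0 = tree_params(),
                     spec = fit_spec(), alpha2 = NULL, r0 = NULL,
                     n_starts = 1, seed = 1,
                     control = minpack.lm::nls.lm.control(maxiter = 100,
                                                          epsfcn = 1e-8),
                     ...) {
  if (!inherits(measurements, "measurement_series"))
    measurements <- measurement_series(measurements)
  if (!inherits(forcing, "forcing_series")) forcing <- forcing_series(forcing)
  if (nrow(measurements) < 3)
    stop("need at least 3 measurements to fit", call. = FALSE)
  ages <- measurements$age
  h_obs <- measurements$height
  if (is.null(r0)) {
    if (!"radius" %in% names(measurements))
      stop("measurements carry no radii: supply r0", call. = FALSE)
    r0 <- measurements$radius[1]
  }
  h0 <- h_obs[1]
  if (is.null(alpha2)) {
    alpha2 <- if ("radius" %in% names(measurements)) {
      n <- nrow(measurements)
      est <- alpha2_from_allometry(
        c(h = h_obs[1], r = measurements$radius[1]),
        c(h = h_obs[n], r = measurements$radius[n]))
      if (!est$valid)
        warning("stand allometry gives alpha2 = ", signif(est$alpha2, 3),
                " outside (0, 1); using it anyway")
      est$alpha2
    } else params0$alpha2
  }
  params0$alpha2 <- alpha2
  free <- spec$free
  ref <- vapply(free, function(nm) params0[[nm]], 0)
  lower <- 1 - spec$rel_bounds
  upper <- 1 + spec$rel_bounds
  init <- tree_state(r0, h0, params0$S1)

  sim_heights <- function(p) {
    tr <- simulate_tree(init, p, forcing, c(ages[1], ages[length(ages)]),
                        times = ages, quiet = TRUE, ...)
    if (attr(tr, "halted") || nrow(tr) < length(ages))
      return(NULL)
    list(h = tr$h[match(ages, tr$time)],
         vol = pi * tr$r[match(ages, tr$time)]^2 * tr$h[match(ages, tr$time)])
  }
  resid_fn <- function(mult) {
    p <- set_free_params(params0, free, ref * mult)
    sm <- sim_heights(p)
    if (is.null(sm)) return(rep(1e6, length(ages)))
    res <- sm$h - h_obs
    if (spec$loss == "height_volume" && "radius" %in% names(measurements)) {
      vol_obs <- pi * measurements$radius^2 * h_obs
      scale <- mean(h_obs) / mean(vol_obs)
      res <- c(res, (sm$vol - vol_obs) * scale)
    }
    res
  }

  if (!length(free)) {
    res0 <- resid_fn(numeric(0))
    sm <- sim_heights(params0)
    out <- list(params = params0, params0 = params0, spec = spec,
                free = free, estimate = numeric(0), reference = numeric(0),
                measurements = measurements, forcing = forcing,
                initial = init, alpha2 = alpha2,
                fitted_heights = sm$h, residuals = res0,
                ssr = sum(res0^2),
                r_squared = r_squared(sm$h, h_obs),
                convergence = list(converged = TRUE,
                                   message = "no free parameters"),
                n_starts = 1)
    class(out) <- "tree_fit"
    return(out)
  }

  starts <- list(rep(1, length(free)))
  if (n_starts > 1) {
    set.seed(seed)
    for (s in seq_len(n_starts - 1))
      starts[[s + 1]] <- stats::runif(length(free), lower + 0.02,
                                      upper - 0.02)
  }
  best <- NULL
  for (st in starts) {
    fit <- minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                              fn = resid_fn, control = control)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  theta <- ref * best$par
  p_fit <- set_free_params(params0, free, theta)
  sm <- sim_heights(p_fit)
  out <- list(params = p_fit, params0 = params0, spec = spec, free = free,
              estimate = stats::setNames(theta, free),
              reference = stats::setNames(ref, free),
              multipliers = stats::setNames(best$par, free),
              measurements = measurements, forcing = forcing,
              initial = init, alpha2 = alpha2,
              fitted_heights = sm$h,
              residuals = sm$h - h_obs,
              ssr = sum((sm$h - h_obs)^2),
              r_squared = r_squared(sm$h, h_obs),
              convergence = list(converged = best$info %in% 1:4,
                                 info = best$info,
                                 message = best$message,
                                 n_iter = best$niter),
              n_starts = n_starts)
  class(out) <- "tree_fit"
  out
}

#' Re-fit only the meristem limit height h2 (site transfer)
#'
#' When the calibrated model is carried to a second site with unknown water
#' potentials, every parameter is kept frozen at its fitted value and only
#' h2 is re-fitted within a margin — a one-dimensional bounded least
#' squares on the new stand's heights.
#'
#' @param fit a [fit_tree()] result (the donor calibration).
#' @param measurements the new stand's [measurement_series()].
#' @param forcing forcing covering the new stand's ages.
#' @param margin relative half-width of the h2 box (default 0.2); 0 returns
#'   the input calibration unchanged.
#' @param ... passed to [fit_tree()].
#' @return A \code{"tree_fit"} on the new stand with only h2 free.
#' @export
refit_h2 <- function(fit, measurements, forcing, margin = 0.2, ...) {
  stopifnot(inherits(fit, "tree_fit"))
  if (margin == 0) return(fit)
  fit_tree(measurements, forcing, params0 = fit$params,
           spec = fit_spec(free = "h2", rel_bound = margin, wide = NULL),
           alpha2 = NULL, ...)
}

#' Forward prediction of a stand (no fitting)
#'
#' Pure simulation from a stand's first measurement with previously
#' calibrated parameters; this is prediction, not fitting. Returns heights
#' and stem volumes (\code{pi * r^2 * h}) at the requested ages.
#'
#' @param params calibrated [tree_params()].
#' @param forcing [forcing_series()] covering the ages.
#' @param initial \code{c(r0, h0)} (m) at \code{ages[1]}, or a
#'   [tree_state()].
#' @param ages ages at which to predict (y); the first is the initial age.
#' @param alpha2 meristem activity ratio for this stand; default
#'   \code{params$alpha2} (e.g. borrowed from the calibration stand).
#' @param ... passed to [simulate_tree()].
#' @return Data frame: \code{age}, \code{height}, \code{radius},
#'   \code{volume}.
#' @export
predict_stand <- function(params, forcing, initial, ages,
                          alpha2 = params$alpha2, ...) {
  params$alpha2 <- alpha2
  init <- if (inherits(initial, "tree_state")) initial
          else tree_state(initial[1], initial[2], params$S1)
  tr <- simulate_tree(init, params, forcing, c(ages[1], ages[length(ages)]),
                      times = sort(unique(ages)), quiet = TRUE, ...)
  i <- match(ages, tr$time)
  data.frame(age = ages, height = tr$h[i], radius = tr$r[i],
             volume = pi * tr$r[i]^2 * tr$h[i])
}

#' @export
coef.tree_fit <- function(object, ...) object$estimate

#' @export
residuals.tree_fit <- function(object, ...) object$residuals

#' @export
print.tree_fit <- function(x, ...) {
  cat("Sink/source-limited tree growth model fit\n")
  cat(sprintf("  %d measurements, ages %.4g-%.4g y; alpha2 = %.3f (fixed)\n",
              nrow(x$measurements), min(x$measurements$age),
              max(x$measurements$age), x$alpha2))
  if (length(x$free)) {
    tab <- data.frame(reference = x$reference, estimate = x$estimate,
                      multiplier = x$multipliers)
    print(signif(tab, 4))
  } else cat("  no free parameters (reference values kept)\n")
  cat(sprintf("  SSR = %.4g m^2,  R^2 = %.4f,  converged: %s\n",
              x$ssr, x$r_squared, x$convergence$converged))
  invisible(x)
}

#' Summary of a tree growth model fit
#'
#' @param object a [fit_tree()] result.
#' @param ... unused.
#' @export
summary.tree_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual sd = %.3f m over %d ages\n",
              stats::sd(object$residuals), length(object$residuals)))
  at_bound <- length(object$free) &&
    any(abs(object$multipliers - (1 - object$spec$rel_bounds)) < 1e-6 |
        abs(object$multipliers - (1 + object$spec$rel_bounds)) < 1e-6)
  if (isTRUE(at_bound))
    cat("  note: at least one parameter sits on its box bound\n")
  invisible(object)
}

#' Predict heights from a fitted model
#'
#' With no new data, returns the fitted heights at the calibration ages.
#' Supply \code{initial} and \code{ages} (and optionally \code{forcing},
#' \code{alpha2}) to predict another stand with the calibrated parameters.
#'
#' @param object a [fit_tree()] result.
#' @param initial \code{c(r0, h0)} of the stand to predict.
#' @param ages prediction ages (y).
#' @param forcing forcing for the predicted stand (default: the
#'   calibration forcing).
#' @param alpha2 activity ratio for the predicted stand (default: the
#'   calibration stand's).
#' @param ... passed to [predict_stand()].
#' @return Data frame as [predict_stand()], or the fitted heights.
#' @export
predict.tree_fit <- function(object, initial = NULL, ages = NULL,
                             forcing = object$forcing,
                             alpha2 = object$alpha2, ...) {
  if (is.null(initial) && is.null(ages)) {
    return(data.frame(age = object$measurements$age,
                      height = object$fitted_heights))
  }
  if (is.null(initial) || is.null(ages))
    stop("supply both initial and ages (or neither)", call. = FALSE)
  predict_stand(object$params, forcing, initial, ages, alpha2 = alpha2, ...)
}

#' @export
plot.tree_fit <- function(x, ...) {
  ages <- x$measurements$age
  dense <- predict_stand(x$params, x$forcing,
                         c(x$initial$r, x$initial$h),
                         seq(min(ages), max(ages)), alpha2 = x$alpha2)
  graphics::plot(ages, x$measurements$height, pch = 1, col = "firebrick",
                 xlab = "age (y)", ylab = "height (m)", ...)
  graphics::lines(dense$age, dense$height, col = "steelblue")
  graphics::legend("bottomright", bty = "n",
                   legend = c("observed", "fitted model"),
                   col = c("firebrick", "steelblue"),
                   pch = c(1, NA), lty = c(NA, 1))
  invisible(x)
}
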