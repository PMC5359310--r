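# Numerical integration of the (r, h, S) system.
#
# The forcing is piecewise constant per year, so the time axis is cut at
# year boundaries and each segment is integrated with the adaptive
# Dormand-Prince 4(5) pair under constant forcing; segment boundaries then
# realise the forcing discontinuities exactly. A fourth auxiliary state
# accumulates the net carbon flux so that mass balance can be audited at
# solver accuracy.

#' Simulate tree growth
#'
#' Integrates the sink/source-limited growth model from an initial state
#' over a span of ages, under annual environmental forcing.
#'
#' The regime (sink- vs source-limited) is re-evaluated at every right-hand
#' side call; the right-hand side is continuous across the regime boundary,
#' so no special event handling is required by the adaptive solver. The
#' storage ratio is kept at or above its critical value S1: integration
#' overshoot below S1 (of the order of the solver tolerance) is clipped at
#' segment ends.
#'
#' @param initial a [tree_state()] at the starting age. By default trees
#'   start at the critical storage, \code{S = S1}.
#' @param params a [tree_params()].
#' @param forcing a [forcing_series()] (or data frame coercible to one)
#'   covering the span.
#' @param t_span numeric length 2: start and end age (y).
#' @param times output ages; default every integer age in the span plus the
#'   endpoints.
#' @param dt_out alternative to \code{times}: output step in years (e.g.
#'   0.1 for within-year regime resolution).
#' @param mode \describe{
#'   \item{"auto"}{the full regime-switching model (default);}
#'   \item{"sink_off"}{the meristem cap removed — growth always equals net
#'     supply, storage pinned at S1 (the sink-off experiment);}
#'   \item{"sink_only"}{growth always at the meristem cap with storage
#'     pinned at S1 — the maximal sink-limited benchmark used for
#'     verification against the closed-form solution.}}
#' @param rtol,atol relative and absolute solver tolerances.
#' @param regime_tol tolerance on S - S1 for regime classification.
#' @param quiet suppress the stress warning (negative growth).
#' @return An object of class \code{"tree_trajectory"}: a data frame with
#'   one row per output age holding the state (\code{r}, \code{h},
#'   \code{S}), the derived pools (\code{Mc}, \code{Sc0}, \code{Mtot}), the
#'   carbon-flux ledger (\code{A}, \code{maintenance}, \code{storage_cost},
#'   \code{growth}, \code{storage_change}), the active \code{regime} and
#'   the running net-flux integral \code{net_flux_integral}. Attributes
#'   carry the parameters, solver metadata and flags.
#' @seealso [cross_check()], [analytic_reference()], [mass_balance_audit()]
#' @export
#' @examples
#' fc <- synth_forcing(48:188, seed = 1)
#' tr <- simulate_tree(tree_state(0.08, 15), tree_params(),
#'                     fc, c(48, 188))
#' tail(as.data.frame(tr)[, c("time", "r", "h", "regime")])
simulate_tree <- function(initial, params, forcing, t_span,
                          times = NULL, dt_out = NULL,
                          mode = c("auto", "sink_off", "sink_only"),
                          rtol = 1e-8, atol = 1e-10, regime_tol = 1e-9,
                          quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(initial, "tree_state"))
  if (!inherits(forcing, "forcing_series")) forcing <- forcing_series(forcing)
  if (length(t_span) != 2 || t_span[2] <= t_span[1])
    stop("t_span must be an increasing pair of ages", call. = FALSE)
  t0 <- t_span[1]; t1 <- t_span[2]
  if (t0 < forcing$year[1] || t1 > forcing$year[nrow(forcing)] + 1)
    stop("forcing does not cover t_span [", t0, ", ", t1, "]; it spans [",
         forcing$year[1], ", ", forcing$year[nrow(forcing)] + 1, "]",
         call. = FALSE)
  if (mode == "sink_off") params$sink_off <- TRUE
  if (is.null(times)) {
    if (is.null(dt_out)) {
      times <- unique(c(t0, seq(ceiling(t0), floor(t1)), t1))
    } else {
      times <- unique(c(seq(t0, t1, by = dt_out), t1))
    }
  }
  times <- sort(unique(times))
  if (times[1] < t0 || times[length(times)] > t1)
    stop("output times must lie inside t_span", call. = FALSE)

  has_ra <- "Ra" %in% names(forcing) && !is.null(params$alpha0)
  alpha2_of_year <- function(i) {
    if (has_ra) alpha2_from_redfarred(forcing$Ra[i], params$alpha0,
                                      params$alpha3)
    else params$alpha2
  }

  S1 <- params$S1
  # numeric RHS over y = (r, h, S, cumulative net flux)
  make_rhs <- function(frow, a2) {
    force(frow); force(a2)
    function(t, y, p) {
      r <- y[1]; h <- y[2]; S <- max(y[3], S1)
      st <- structure(list(r = r, h = h, S = S), class = "tree_state")
      if (mode == "sink_only") {
        growth <- sink_cap(st, params)
        cs <- carbon_supply(st, frow, params)
        dr <- growth / (2 * params$g1 * pi * r * h * (1 + a2))
        dh <- 2 * a2 * (h / r) * dr
        return(list(c(dr, dh, 0, unname(cs[["supply"]]))))
      }
      out <- tree_rhs(st, frow, params, alpha2 = a2, tol = regime_tol)
      led <- out$ledger
      list(c(out$rates, led$A - led$maintenance - led$storage_cost))
    }
  }

  cuts <- sort(unique(c(t0, t1,
                        seq(ceiling(t0), floor(t1))[
                          seq(ceiling(t0), floor(t1)) > t0 &
                            seq(ceiling(t0), floor(t1)) < t1])))
  y <- c(initial$r, initial$h, max(initial$S, S1), 0)
  rows <- list()
  n_eval <- 0L
  halted <- FALSE
  rk <- deSolve::rkMethod("ode45")
  for (k in seq_len(length(cuts) - 1)) {
    a <- cuts[k]; b <- cuts[k + 1]
    i <- forcing_index(forcing, a)
    frow <- as.list(forcing[i, , drop = FALSE])
    a2 <- alpha2_of_year(i)
    seg_times <- sort(unique(c(a, times[times > a & times < b], b)))
    sol <- deSolve::ode(y = y, times = seg_times, func = make_rhs(frow, a2),
                        parms = NULL, method = rk, rtol = rtol, atol = atol,
                        hmax = 1)
    n_eval <- n_eval + attr(sol, "istate")[3]
    keep <- seg_times %in% times
    if (k > 1) keep <- keep & seg_times > a   # segment start already emitted
    if (any(keep)) {
      for (j in which(keep)) {
        rows[[length(rows) + 1L]] <-
          c(time = seg_times[j], unname(sol[j, 2:5]), year_row = i,
            alpha2 = a2)
      }
    }
    y <- unname(sol[nrow(sol), 2:5])
    y[3] <- max(y[3], S1)  # clip tolerance-level overshoot below S1
    if (!all(is.finite(y)) || y[1] <= 0 || y[2] <= 0) {
      warning(sprintf(
        "simulation halted at age %.3f: state collapsed (r = %.3g, h = %.3g)",
        b, y[1], y[2]))
      halted <- TRUE
      break
    }
  }

  m <- do.call(rbind, rows)
  traj <- data.frame(time = m[, "time"], r = m[, 2], h = m[, 3],
                     S = pmax(m[, 4], S1), net_flux_integral = m[, 5])
  # per-output-row ledger and regime
  led <- vector("list", nrow(traj))
  for (j in seq_len(nrow(traj))) {
    st <- structure(list(r = traj$r[j], h = traj$h[j], S = traj$S[j]),
                    class = "tree_state")
    frow <- as.list(forcing[m[j, "year_row"], , drop = FALSE])
    if (mode == "sink_only") {
      cs <- carbon_supply(st, frow, params)
      g <- sink_cap(st, params)
      led[[j]] <- list(A = unname(cs[["A"]]),
                       maintenance = unname(cs[["maintenance"]]),
                       storage_cost = unname(cs[["storage_cost"]]),
                       growth = g,
                       storage_change = unname(cs[["supply"]]) - g,
                       regime = "sink")
    } else {
      led[[j]] <- flux_ledger(st, frow, params, regime_tol)
    }
  }
  traj$A <- vapply(led, `[[`, 0, "A")
  traj$maintenance <- vapply(led, `[[`, 0, "maintenance")
  traj$storage_cost <- vapply(led, `[[`, 0, "storage_cost")
  traj$growth <- vapply(led, `[[`, 0, "growth")
  traj$storage_change <- vapply(led, `[[`, 0, "storage_change")
  traj$regime <- vapply(led, `[[`, "", "regime")
  vol <- pi * traj$r^2 * traj$h
  traj$Mc <- params$g1 * vol
  traj$Sc0 <- (traj$S - S1) * params$g1 * vol / (1 + S1)
  traj$Mtot <- traj$Mc + traj$Sc0
  traj$alpha2 <- m[, "alpha2"]

  stress <- any(traj$growth < 0)
  if (stress && !quiet)
    warning("stress: negative structural growth along the trajectory ",
            "(assimilation below maintenance at critical storage)")
  structure(traj,
            class = c("tree_trajectory", "data.frame"),
            params = params, mode = mode, initial = initial,
            t_span = c(t0, t1),
            solver = list(method = "ode45 (Dormand-Prince 4(5))",
                          rtol = rtol, atol = atol, hmax = 1,
                          n_rhs_eval = unname(n_eval)),
            halted = halted, stress = stress)
}

#' @export
print.tree_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "Tree growth trajectory: age %.4g to %.4g y (%d output rows, mode '%s')\n",
    x$time[1], x$time[n], n, attr(x, "mode")))
  cat(sprintf("  r: %.4g -> %.4g m,  h: %.4g -> %.4g m,  S: %.4g -> %.4g\n",
              x$r[1], x$r[n], x$h[1], x$h[n], x$S[1], x$S[n]))
  reg <- table(x$regime)
  cat("  regime rows:", paste(names(reg), reg, sep = " = ",
                              collapse = ", "), "\n")
  if (attr(x, "halted")) cat("  NOTE: simulation halted early\n")
  if (attr(x, "stress")) cat("  NOTE: stress (negative growth) occurred\n")
  invisible(x)
}

#' @export
summary.tree_trajectory <- function(object, ...) {
  sw <- which(diff(object$regime == "sink") != 0)
  cat("Simulated tree growth\n")
  print(object)
  if (length(sw))
    cat("  regime switches near ages:",
        paste(round(object$time[sw + 1], 1), collapse = ", "), "\n")
  aud <- mass_balance_audit(object)
  cat(sprintf("  mass-balance audit: |dMtot - int(net flux)| = %.3g kg (rel %.3g)\n",
              aud[["abs"]], aud[["rel"]]))
  invisible(object)
}

#' @export
plot.tree_trajectory <- function(x, which = c("h", "r", "S"), ...) {
  which <- match.arg(which)
  ylab <- switch(which, h = "height (m)", r = "radius (m)",
                 S = "storage ratio")
  col <- ifelse(x$regime == "sink", "firebrick", "steelblue")
  graphics::plot(x$time, x[[which]], type = "l", xlab = "age (y)",
                 ylab = ylab, ...)
  graphics::points(x$time, x[[which]], col = col, pch = 20, cex = 0.5)
  graphics::legend("bottomright", pch = 20,
                   col = c("steelblue", "firebrick"),
                   legend = c("source-limited", "sink-limited"), bty = "n")
  invisible(x)
}

#' Mass-balance audit of a trajectory
#'
#' Total carbon change over the run must equal the time integral of the net
#' flux (assimilation minus maintenance and storage respiration). The
#' integral is accumulated as an auxiliary state during integration, so the
#' audit discrepancy measures integrator consistency and should sit at the
#' solver tolerance.
#'
#' @param traj a [simulate_tree()] trajectory.
#' @return Named vector: absolute (kg) and relative discrepancy.
#' @export
mass_balance_audit <- function(traj) {
  dM <- traj$Mtot[nrow(traj)] - traj$Mtot[1]
  fl <- traj$net_flux_integral[nrow(traj)] - traj$net_flux_integral[1]
  c(abs = abs(dM - fl), rel = abs(dM - fl) / max(abs(dM), abs(fl), 1e-12))
}

#' Trapezoidal cross-check of the adaptive integrator
#'
#' Re-solves the same problem with an implicit trapezoidal-rule integrator
#' on a fixed step (fixed-point iteration per step) and reports the maximum
#' relative height discrepancy against the adaptive solution at the common
#' integer ages. A verification utility: the two methods are independent
#' discretisations of the same right-hand side.
#'
#' @inheritParams simulate_tree
#' @param dt fixed trapezoidal step, y (<= 0.5 recommended; default 0.1).
#' @return List with \code{max_rel_h_discrepancy}, and the two height
#'   series (\code{ages}, \code{h_rk45}, \code{h_trap}).
#' @export
cross_check <- function(initial, params, forcing, t_span, dt = 0.1,
                        mode = "auto", rtol = 1e-8, atol = 1e-10) {
  tr <- simulate_tree(initial, params, forcing, t_span, mode = mode,
                      rtol = rtol, atol = atol, quiet = TRUE)
  ages <- tr$time[tr$time == round(tr$time)]
  trap <- trapezoid_solve(initial, params, forcing, t_span, dt, mode)
  h_trap <- stats::approx(trap$time, trap$h, xout = ages)$y
  h_rk <- tr$h[match(ages, tr$time)]
  list(max_rel_h_discrepancy = max(abs(h_trap - h_rk) / h_rk),
       ages = ages, h_rk45 = h_rk, h_trap = h_trap)
}

# fixed-step implicit trapezoidal rule on (r, h, S); steps aligned to year
# boundaries so the piecewise-constant forcing is honoured exactly
trapezoid_solve <- function(initial, params, forcing, t_span, dt = 0.1,
                            mode = "auto", max_iter = 50, fp_tol = 1e-13) {
  if (!inherits(forcing, "forcing_series")) forcing <- forcing_series(forcing)
  if (mode == "sink_off") params$sink_off <- TRUE
  S1 <- params$S1
  rhs <- function(y, frow) {
    st <- structure(list(r = y[1], h = y[2], S = max(y[3], S1)),
                    class = "tree_state")
    if (mode == "sink_only") {
      g <- sink_cap(st, params)
      dr <- g / (2 * params$g1 * pi * y[1] * y[2] * (1 + params$alpha2))
      c(dr, 2 * params$alpha2 * (y[2] / y[1]) * dr, 0)
    } else {
      unname(tree_rhs(st, frow, params)$rates)
    }
  }
  t0 <- t_span[1]; t1 <- t_span[2]
  cuts <- sort(unique(c(t0, t1, seq(ceiling(t0), floor(t1)))))
  cuts <- cuts[cuts >= t0 & cuts <= t1]
  y <- c(initial$r, initial$h, max(initial$S, S1))
  out_t <- t0; out_y <- matrix(y, nrow = 1)
  for (k in seq_len(length(cuts) - 1)) {
    a <- cuts[k]; b <- cuts[k + 1]
    frow <- as.list(forcing[forcing_index(forcing, a), , drop = FALSE])
    nstep <- max(1L, ceiling((b - a) / dt))
    h_step <- (b - a) / nstep
    for (s in seq_len(nstep)) {
      f0 <- rhs(y, frow)
      ynew <- y + h_step * f0          # explicit Euler predictor
      for (it in seq_len(max_iter)) {
        yprev <- ynew
        ynew <- y + h_step / 2 * (f0 + rhs(ynew, frow))
        if (max(abs(ynew - yprev) / pmax(abs(ynew), 1e-12)) < fp_tol) break
      }
      y <- ynew
      y[3] <- max(y[3], S1)
    }
    out_t <- c(out_t, b); out_y <- rbind(out_y, y)
  }
  data.frame(time = out_t, r = out_y[, 1], h = out_y[, 2], S = out_y[, 3])
}

#' Closed-form reference trajectory (simplified sink-limited regime)
#'
#' In the purely sink-limited benchmark with the height limit far away
#' (h << h2), a lateral-dominated meristem (2*pi*r*h >> pi*r^2/t_ratio) and
#' storage at its critical value, the radius grows linearly:
#' \deqn{r(t) = r_0 + \frac{k_{lat}}{1 + \alpha_2} t, \qquad
#'       h(t) = \gamma r(t)^{2\alpha_2}.}
#' Used as the analytic oracle for integrator verification.
#'
#' @inheritParams simulate_tree
#' @param times output ages (absolute, starting at \code{t0}).
#' @param t0 age corresponding to the initial state.
#' @param max_h2_frac,max_apical_frac validity guards: error if the final
#'   height exceeds \code{max_h2_frac * h2} or the apical meristem term
#'   exceeds \code{max_apical_frac} of the lateral term at the start.
#' @return Data frame with \code{time}, \code{r}, \code{h}.
#' @export
analytic_reference <- function(initial, params, times, t0 = times[1],
                               max_h2_frac = 0.05, max_apical_frac = 0.01) {
  gamma <- allometry_gamma(initial$r, initial$h, params$alpha2)
  slope <- params$k_lat / (1 + params$alpha2)
  r <- initial$r + slope * (times - t0)
  h <- allometric_height(r, gamma, params$alpha2)
  apical_frac <- initial$r / (2 * initial$h * params$t_ratio)
  if (max(h) > max_h2_frac * params$h2)
    stop("analytic reference invalid: height reaches ",
         signif(max(h) / params$h2 * 100, 3), "% of h2 (limit ",
         max_h2_frac * 100, "%)", call. = FALSE)
  if (apical_frac > max_apical_frac)
    stop("analytic reference invalid: apical meristem term is ",
         signif(apical_frac * 100, 3), "% of the lateral term", call. = FALSE)
  data.frame(time = times, r = r, h = h)
}
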