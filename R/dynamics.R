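# Regime-switching carbon allocation.
#
# Supply  = A - C*pi*h*r^2 - C2*pi*S*h*r^2   (assimilation minus costs)
# Demand  = sink_cap (meristem-sustained maximum)
# SINK_LIMITED  : supply > demand, or S > S1 (storage can bridge the gap);
#                 growth runs at the storage-discounted cap, the residual
#                 supply goes to (or is drawn from) storage.
# SOURCE_LIMITED: supply <= demand and S at the critical floor S1;
#                 growth equals supply (possibly negative), storage frozen.

#' Net carbon supply and maintenance costs
#'
#' @param state a [tree_state()].
#' @param forcing one forcing row (list or data frame row with T, Q1, Cg).
#' @param params a [tree_params()].
#' @return Named vector: assimilation \code{A}, \code{maintenance}
#'   (= C*pi*h*r^2), \code{storage_cost} (= C2*pi*S*h*r^2) and the net
#'   \code{supply} = A - maintenance - storage_cost (all kg/y).
#' @export
carbon_supply <- function(state, forcing, params) {
  A <- assimilation(state, forcing, params)
  hr2 <- pi * state$h * state$r^2
  maint <- params$C_over_pi * hr2
  scost <- params$C2_over_pi * state$S * hr2
  c(A = A, maintenance = maint, storage_cost = scost,
    supply = A - maint - scost)
}

#' Classify the limiting process for growth
#'
#' Growth is sink-limited when the net carbon supply exceeds the meristem
#' cap, or when the storage ratio sits above its critical value S1 (stored
#' carbon can then sustain the cap); otherwise it is source-limited.
#'
#' @inheritParams carbon_supply
#' @param tol tolerance on S - S1 for the boundary classification.
#' @return \code{"sink"} or \code{"source"} (character scalar).
#' @export
#' @examples
#' st <- tree_state(0.05, 3, S = 0.2)
#' classify_regime(st, list(T = 18, Q1 = 300, Cg = 300), tree_params())
classify_regime <- function(state, forcing, params, tol = 1e-9) {
  if (params$sink_off) return("source")
  cs <- carbon_supply(state, forcing, params)
  cap <- sink_cap(state, params)
  if (cs[["supply"]] > cap || state$S > params$S1 + tol) "sink" else "source"
}

#' Growth rates in the two regimes
#'
#' In the sink-limited regime structural growth runs at the meristem cap
#' discounted by excess storage (new tissue is built at the current storage
#' density): \code{dMc/dt = cap / (1 + (S - S1)/(1 + S1))}, which equals the
#' cap exactly at S = S1. In the source-limited regime growth equals the net
#' supply, \code{dMc/dt = A - C*pi*h*r^2 - C2*pi*S*h*r^2}, which can be
#' negative under stress (assimilation below maintenance at critical
#' storage).
#'
#' @inheritParams carbon_supply
#' @return Structural growth rate dMc/dt, kg/y.
#' @export
growth_rate_sink <- function(state, params) {
  sink_cap(state, params) / (1 + (state$S - params$S1) / (1 + params$S1))
}

#' @rdname growth_rate_sink
#' @export
growth_rate_source <- function(state, forcing, params) {
  unname(carbon_supply(state, forcing, params)[["supply"]])
}

#' Storage pool rate in the sink-limited regime
#'
#' Whatever net supply is not consumed by structural growth changes the
#' above-critical storage pool: \code{dSc0/dt = supply - dMc/dt}. Negative
#' values deplete storage (it is then sustaining growth and/or maintenance).
#'
#' @inheritParams carbon_supply
#' @param dMc_dt structural growth rate (kg/y), normally
#'   [growth_rate_sink()].
#' @return dSc0/dt, kg/y.
#' @export
storage_rate <- function(state, forcing, params, dMc_dt) {
  unname(carbon_supply(state, forcing, params)[["supply"]]) - dMc_dt
}

#' Per-step carbon flux ledger
#'
#' Evaluates every flux of the carbon balance at one state: assimilation,
#' maintenance, storage respiration, structural growth and storage change,
#' plus the active regime. The ledger closes by construction:
#' \code{A - maintenance - storage_cost = growth + storage_change}.
#'
#' @inheritParams classify_regime
#' @return Named list with \code{A}, \code{maintenance},
#'   \code{storage_cost}, \code{growth}, \code{storage_change},
#'   \code{regime}.
#' @export
flux_ledger <- function(state, forcing, params, tol = 1e-9) {
  cs <- carbon_supply(state, forcing, params)
  regime <- if (!params$sink_off &&
                (cs[["supply"]] > sink_cap(state, params) ||
                 state$S > params$S1 + tol)) "sink" else "source"
  if (regime == "sink") {
    growth <- growth_rate_sink(state, params)
    dSc0 <- cs[["supply"]] - growth
  } else {
    growth <- cs[["supply"]]
    dSc0 <- 0
  }
  list(A = unname(cs[["A"]]), maintenance = unname(cs[["maintenance"]]),
       storage_cost = unname(cs[["storage_cost"]]), growth = growth,
       storage_change = dSc0, regime = regime)
}

#' Right-hand side of the growth ODE system
#'
#' Converts the mass balance into rates for the state vector (r, h, S).
#' Height is coupled to radius by the meristem activity ratio,
#' \code{dh/dt = 2 * alpha2 * (h/r) * dr/dt}, so
#' \code{dMc/dt = d(g1*pi*r^2*h)/dt = 2*g1*pi*r*h*(1 + alpha2) * dr/dt}.
#' The storage-ratio rate is recovered from dSc0/dt by the product rule on
#' \code{Sc0 = (S - S1)*g1*pi*h*r^2/(1 + S1)}; it is 0 in the
#' source-limited regime.
#'
#' @inheritParams classify_regime
#' @param alpha2 meristem activity ratio for this step (defaults to
#'   \code{params$alpha2}; the red:far-red control supplies it per step when
#'   Ra forcing is present).
#' @return List with numeric \code{rates} (dr/dt, dh/dt, dS/dt), the
#'   \code{ledger} and the \code{regime}.
#' @export
tree_rhs <- function(state, forcing, params, alpha2 = params$alpha2,
                     tol = 1e-9) {
  r <- state$r; h <- state$h
  if (!is.finite(r) || !is.finite(h) || r <= 0 || h <= 0)
    stop("invalid state: r and h must be positive", call. = FALSE)
  led <- flux_ledger(state, forcing, params, tol)
  dMc <- led$growth
  dr <- dMc / (2 * params$g1 * pi * r * h * (1 + alpha2))
  dh <- 2 * alpha2 * (h / r) * dr
  if (led$regime == "sink") {
    geom <- (state$S - params$S1) * (r^2 * dh + 2 * r * h * dr)
    dS <- ((1 + params$S1) * led$storage_change / (params$g1 * pi) - geom) /
      (h * r^2)
  } else {
    dS <- 0
  }
  list(rates = c(dr = dr, dh = dh, dS = dS), ledger = led,
       regime = led$regime)
}
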