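#' Allometric height-radius coupling
#'
#' The model's only internal control is the ratio alpha2 of apical to lateral
#' meristematic activity, which ties relative height growth to relative
#' radial growth, \code{dh/h = 2 * alpha2 * dr/r}. With constant alpha2 this
#' integrates to the power law \code{h = gamma * r^(2*alpha2)}.
#'
#' \code{allometry_gamma()} computes the allometric constant from an initial
#' (or any) size; \code{allometric_height()} evaluates the power law.
#'
#' @param r0,h0 reference radius and height, m (> 0).
#' @param r radius at which to evaluate the height, m (> 0).
#' @param gamma allometric constant (> 0).
#' @param alpha2 meristem activity ratio (> 0).
#' @return \code{allometry_gamma()}: the constant
#'   \code{gamma = h0 / r0^(2*alpha2)}; \code{allometric_height()}: the
#'   height \code{gamma * r^(2*alpha2)} (m). Both vectorised in the size
#'   arguments.
#' @export
#' @examples
#' g <- allometry_gamma(0.1, 10, 0.4)
#' allometric_height(0.2, g, 0.4)   # ~17.4 m
allometry_gamma <- function(r0, h0, alpha2) {
  if (any(r0 <= 0) || any(h0 <= 0) || any(alpha2 <= 0))
    stop("r0, h0 and alpha2 must be positive", call. = FALSE)
  h0 / r0^(2 * alpha2)
}

#' @rdname allometry_gamma
#' @export
allometric_height <- function(r, gamma, alpha2) {
  if (any(r <= 0) || any(gamma <= 0))
    stop("r and gamma must be positive", call. = FALSE)
  gamma * r^(2 * alpha2)
}

#' Meristem activity ratio from the red:far-red light signal
#'
#' A low red:far-red ratio signals shading by neighbours; the tree responds
#' by shifting activity towards the apical meristem (height growth):
#' \code{alpha2 = alpha0 * exp(-alpha3 * Ra)}. \code{alpha0} is the
#' mechanical ceiling; \code{alpha0 * exp(-alpha3)} is the unshaded value
#' (at Ra = 1).
#'
#' @param Ra red:far-red ratio, dimensionless (>= 0). Vectorised.
#' @param alpha0 ceiling of alpha2 (> 0).
#' @param alpha3 scale of the response (>= 0).
#' @return alpha2 values, strictly decreasing in Ra, bounded by alpha0.
#' @export
alpha2_from_redfarred <- function(Ra, alpha0, alpha3) {
  if (any(Ra < 0)) stop("Ra must be >= 0", call. = FALSE)
  if (alpha0 <= 0 || alpha3 < 0)
    stop("need alpha0 > 0 and alpha3 >= 0", call. = FALSE)
  alpha0 * exp(-alpha3 * Ra)
}

#' Estimate the meristem activity ratio from two stand measurements
#'
#' Inverts the allometric power law on a pair of (height, radius)
#' measurements: \code{alpha2 = log(hB/hA) / (2 * log(rB/rA))}. Values far
#' outside the plausible beech range (0.34-0.43, more loosely (0, 1)) are
#' flagged rather than rejected.
#'
#' @param m1,m2 numeric vectors with named elements \code{h} and \code{r}
#'   (m), e.g. \code{c(h = 10, r = 0.1)}; ages are not needed.
#' @return A list with \code{alpha2} and \code{valid} (TRUE when the
#'   estimate lies in (0, 1)).
#' @export
#' @examples
#' alpha2_from_allometry(c(h = 10, r = 0.1), c(h = 17.41, r = 0.2))
alpha2_from_allometry <- function(m1, m2) {
  h <- c(m1[["h"]], m2[["h"]]); r <- c(m1[["r"]], m2[["r"]])
  if (any(h <= 0) || any(r <= 0))
    stop("heights and radii must be positive", call. = FALSE)
  if (r[1] == r[2])
    stop("radii are identical: allometric exponent undefined", call. = FALSE)
  a2 <- log(h[2] / h[1]) / (2 * log(r[2] / r[1]))
  list(alpha2 = a2, valid = a2 > 0 && a2 < 1)
}

#' Environmental response factors of assimilation
#'
#' Carbon assimilation is a separable product of saturating or parabolic
#' responses, each normalised to [0, 1]:
#' \describe{
#'   \item{temperature_factor}{an asymmetric parabola
#'     \code{1 - ((T - Topt)/Ti)^2} with half-width \code{Ti_above} for
#'     T > Topt and \code{Ti_below} otherwise, clamped below at 0.}
#'   \item{co2_factor}{\code{1 - exp(-Cg/Cr)}, saturating in the CO2 mixing
#'     ratio.}
#'   \item{par_factor}{\code{1 - exp(-Q1/Qr)}, saturating in PAR.}
#'   \item{hydraulic_factor}{\code{(h1 - beta*h)/h1}, the linear decline of
#'     leaf water potential with height, clamped below at 0. It reaches 0 at
#'     h = h1/beta.}
#' }
#' All are vectorised in their first argument.
#'
#' @param T_C air temperature, degrees C.
#' @param Topt optimal temperature, degrees C.
#' @param Ti_above,Ti_below parabola half-widths, degrees C (> 0).
#' @param Cg atmospheric CO2 mixing ratio, ppm (>= 0).
#' @param Cr CO2 saturation constant, ppm (> 0).
#' @param Q1 PAR, W/m^2 (>= 0).
#' @param Qr PAR saturation constant, W/m^2 (> 0).
#' @param h tree height, m (>= 0).
#' @param h1 photosynthesis limit height, m (> 0).
#' @param beta canopy geometry coefficient in (0, 1].
#' @return Dimensionless factors in [0, 1].
#' @export
temperature_factor <- function(T_C, Topt = 18, Ti_above = 21,
                               Ti_below = 25) {
  if (Ti_above <= 0 || Ti_below <= 0)
    stop("Ti half-widths must be positive", call. = FALSE)
  Ti <- ifelse(T_C > Topt, Ti_above, Ti_below)
  pmax(0, 1 - ((T_C - Topt) / Ti)^2)
}

#' @rdname temperature_factor
#' @export
co2_factor <- function(Cg, Cr = 500) {
  if (Cr <= 0) stop("Cr must be positive", call. = FALSE)
  if (any(Cg < 0)) stop("Cg must be >= 0", call. = FALSE)
  1 - exp(-Cg / Cr)
}

#' @rdname temperature_factor
#' @export
par_factor <- function(Q1, Qr = 1000) {
  if (Qr <= 0) stop("Qr must be positive", call. = FALSE)
  if (any(Q1 < 0)) stop("Q1 must be >= 0", call. = FALSE)
  1 - exp(-Q1 / Qr)
}

#' @rdname temperature_factor
#' @export
hydraulic_factor <- function(h, h1 = 90, beta = 0.75) {
  if (h1 <= 0) stop("h1 must be positive", call. = FALSE)
  if (any(h < 0)) stop("h must be >= 0", call. = FALSE)
  pmax(0, (h1 - beta * h) / h1)
}

#' Whole-tree carbon assimilation
#'
#' Net assimilation (gross photosynthesis minus the proportional foliage
#' respiration) scales with the crown projection area (r^2) and crown depth
#' (h), modulated by the four environmental factors:
#' \deqn{A = Amax (1 - e^{-Cg/Cr}) (1 - e^{-Q1/Qr})
#'   (1 - ((T - Topt)/Ti)^2) \frac{h1 - \beta h}{h1} \pi r^2 h}
#' with Amax the maximal assimilation per unit of crown volume.
#'
#' @param state a [tree_state()].
#' @param forcing a one-row data frame (or named list) with \code{T}
#'   (degrees C), \code{Q1} (W/m^2) and \code{Cg} (ppm).
#' @param params a [tree_params()].
#' @return Assimilation flux, kg carbon / y (>= 0).
#' @export
#' @examples
#' st <- tree_state(0.2, 20)
#' assimilation(st, list(T = 18, Q1 = 800, Cg = 380), tree_params())
assimilation <- function(state, forcing, params) {
  fT <- temperature_factor(forcing$T, params$Topt, params$Ti_above,
                           params$Ti_below)
  fC <- co2_factor(forcing$Cg, params$Cr)
  fQ <- par_factor(forcing$Q1, params$Qr)
  fH <- hydraulic_factor(state$h, params$h1, params$beta)
  params$Amax * fC * fQ * fT * fH * state$r^2 * state$h
}

#' Meristem volume (per unit lateral thickness)
#'
#' The apical meristem is a disc of area pi*r^2 and thickness t1; the
#' lateral meristem (vascular cambium) a sleeve of area 2*pi*r*h and
#' thickness t2. Since only the composites t2*Rmax0/g1 and t2/t1 are
#' identifiable, the volume is returned with the lateral thickness factored
#' out: \code{Vme/t2 = pi*r^2/t_ratio + 2*pi*r*h}.
#'
#' @param r stem radius, m (> 0).
#' @param h stem height, m (> 0).
#' @param t_ratio lateral:apical thickness ratio t2/t1 (> 0).
#' @return Vme/t2, m^2 (a volume per unit thickness). Vectorised.
#' @export
meristem_volume <- function(r, h, t_ratio = 1) {
  if (any(r <= 0) || any(h <= 0)) stop("r and h must be positive",
                                       call. = FALSE)
  if (t_ratio <= 0) stop("t_ratio must be positive", call. = FALSE)
  pi * r^2 / t_ratio + 2 * pi * r * h
}

#' Maximal meristem-sustained growth (the sink cap)
#'
#' The intrinsic limit on structural growth: meristem output per volume
#' (Rmax) declines linearly with height through falling water potential and
#' stops at h2, so
#' \code{cap = g1 * k_lat * max(0, (h2 - h)/h2) * (Vme/t2)} (kg/y). When the
#' tree is at its critical storage this cap is the realised sink-limited
#' growth rate; excess storage discounts it (see [growth_rate_sink()]).
#'
#' @param state a [tree_state()].
#' @param params a [tree_params()]. With \code{sink_off = TRUE} the cap is
#'   \code{Inf}.
#' @return Maximal structural growth rate, kg carbon / y (>= 0).
#' @export
sink_cap <- function(state, params) {
  if (params$sink_off) return(Inf)
  vme <- meristem_volume(state$r, state$h, params$t_ratio)
  params$g1 * params$k_lat * max(0, (params$h2 - state$h) / params$h2) * vme
}
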