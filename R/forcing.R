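#' Validate an environmental forcing series
#'
#' A forcing series is a data frame with one row per year of tree age (or
#' calendar year) carrying the annual drivers of the model: mean
#' growing-season temperature \code{T} (degrees C), PAR \code{Q1} (W/m^2),
#' atmospheric CO2 mixing ratio \code{Cg} (ppm) and optionally the
#' red:far-red ratio \code{Ra}. Forcing is treated as piecewise constant
#' over each interval [year, year + 1).
#'
#' @param x a data frame with columns \code{year}, \code{T}, \code{Q1},
#'   \code{Cg} and optionally \code{Ra}.
#' @return The validated data frame with class \code{"forcing_series"}
#'   prepended.
#' @export
forcing_series <- function(x) {
  x <- as.data.frame(x)
  need <- c("year", "T", "Q1", "Cg")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("forcing is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in intersect(c(need, "Ra"), names(x))) {
    if (!is.numeric(x[[nm]]))
      stop("forcing column '", nm, "' is not numeric", call. = FALSE)
    if (anyNA(x[[nm]]))
      stop("forcing column '", nm, "' has missing values (rows ",
           paste(which(is.na(x[[nm]])), collapse = ", "), ")",
           call. = FALSE)
  }
  if (is.unsorted(x$year, strictly = TRUE))
    stop("forcing years must be strictly increasing", call. = FALSE)
  if (nrow(x) > 1 && any(diff(x$year) != 1)) {
    gap <- x$year[which(diff(x$year) != 1)[1]]
    stop("forcing has a gap after year ", gap,
         ": annual coverage required", call. = FALSE)
  }
  if (any(x$Q1 < 0)) stop("Q1 must be >= 0", call. = FALSE)
  if (any(x$Cg <= 0)) stop("Cg must be > 0", call. = FALSE)
  if ("Ra" %in% names(x) && any(x$Ra < 0))
    stop("Ra must be >= 0", call. = FALSE)
  class(x) <- unique(c("forcing_series", class(x)))
  x
}

# forcing row index for time t (piecewise constant on [year, year+1))
forcing_index <- function(forcing, t) {
  i <- findInterval(t, forcing$year)
  if (any(i < 1) || any(t > forcing$year[nrow(forcing)] + 1))
    stop("forcing does not cover time ", t[i < 1 | i > nrow(forcing)][1],
         call. = FALSE)
  pmin(i, nrow(forcing))
}
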