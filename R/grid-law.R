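#' Stationary residual-age law of a renewal process
#'
#' The age-since-last-event distribution of a stationary renewal process
#' with inter-event law `law`: density `P(T > a) / E[T]`.  This is the
#' natural "the process has been running for a long time" initial age
#' distribution, and it is always compatible with conditioning the residual
#' duration on exceeding the age.
#'
#' @param law A [duration_law()] with finite positive mean.
#' @return A `duration_law` (exponential laws are their own residual law).
#' @export
residual_law <- function(law) {
  stopifnot(inherits(law, "duration_law"))
  m <- law_mean(law)
  if (!is.finite(m) || m <= 0) {
    stop("the residual law needs a finite positive mean", call. = FALSE)
  }
  if (law$family == "exponential" && law$shift == 0) return(law)
  up <- law_upper(law, 1e-9)
  a <- seq(0, up, length.out = 8192L)
  grid_law(a, law_survival(law, a))
}

#' Duration law from a tabulated density
#'
#' Builds a [duration_law()] from density values on an age grid (trapezoid
#' normalized).  Used to initialize a model at a computed endemic
#' equilibrium, whose age profiles are not in any parametric family.
#'
#' @param a Increasing grid of non-negative ages.
#' @param density Non-negative density values on `a`.
#' @return A `duration_law` with family `"grid"`.
#' @export
grid_law <- function(a, density) {
  stopifnot(is.numeric(a), is.numeric(density), length(a) == length(density),
            length(a) >= 2L, all(diff(a) > 0), all(density >= 0),
            a[1] >= 0)
  da <- diff(a)
  cell <- c(0, cumsum(da * (density[-1] + density[-length(a)]) / 2))
  tot <- cell[length(cell)]
  if (tot <= 0) stop("density integrates to zero", call. = FALSE)
  density <- density / tot
  cdf <- cell / tot
  # strictly increasing knots for inversion
  keep <- c(TRUE, diff(cdf) > 1e-15)
  qfun <- stats::approxfun(cdf[keep], a[keep], rule = 2)
  dfun <- stats::approxfun(a, density, yleft = 0, yright = 0)
  sfun <- stats::approxfun(a, 1 - cdf, yleft = 1, yright = 0)
  m <- sum(da * ((a * density)[-1] + (a * density)[-length(a)]) / 2)
  structure(list(
    family = "grid", pars = list(n = length(a)), shift = 0, mean = m,
    has_density = TRUE, is_point_mass = FALSE, is_infinite = FALSE,
    density = function(x) dfun(x),
    survival = function(x) pmin(pmax(sfun(x), 0), 1),
    quantile = function(p) qfun(p),
    sample = function(n) qfun(stats::runif(n))
  ), class = "duration_law")
}
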