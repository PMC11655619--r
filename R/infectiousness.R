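#' Infectiousness laws
#'
#' An `infectiousness_law` is a distribution over random infectiousness
#' curves: each infection draws an infectious period `T_I` from a
#' [duration_law()] and transmits at rate `lambda(a)` at time-since-infection
#' `a < T_I`.  By convention `lambda(a) = 0` for `a >= T_I`, so the mean
#' curve `E[lambda(a)]` already contains the survival factor `P(T_I > a)`
#' and the basic reproduction number is its plain integral.
#'
#' Two kinds are built in:
#' * `"constant"`: `lambda(a) = rate` while infectious (the classical
#'   compartmental assumption);
#' * `"shape"`: a deterministic, bounded profile `shape_fun(a)` evaluated
#'   while infectious, allowing e.g. a viral-load-like rise and fall.
#'
#' @param kind `"constant"` or `"shape"`.
#' @param duration A [duration_law()] for the infectious period `T_I`.
#' @param rate Transmission rate while infectious (`kind = "constant"`).
#' @param shape_fun Vectorized non-negative function of age
#'   (`kind = "shape"`).
#' @param lambda_max Upper bound on the curve; required for `"shape"` unless
#'   it can be found by profiling `shape_fun` on the support of `T_I`.
#' @return An object of class `infectiousness_law`.
#' @examples
#' inf <- infectiousness_law("constant", rate = 0.6,
#'                           duration = duration_law("exponential", rate = 0.2))
#' basic_reproduction_number(inf) # 3
#' @export
infectiousness_law <- function(kind = c("constant", "shape"), duration,
                               rate = NULL, shape_fun = NULL,
                               lambda_max = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(duration, "duration_law"))
  if (kind == "constant") {
    stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
    shape_fun <- NULL
    lambda_max <- rate
  } else {
    stopifnot(is.function(shape_fun))
    if (is.null(lambda_max)) {
      up <- law_upper(duration)
      if (!is.finite(up)) {
        stop("lambda_max must be given for a shape curve with unbounded T_I",
             call. = FALSE)
      }
      lambda_max <- max(shape_fun(seq(0, up, length.out = 4096)))
    }
    stopifnot(is.finite(lambda_max), lambda_max >= 0)
  }
  structure(list(kind = kind, duration = duration, rate = rate,
                 shape_fun = shape_fun, lambda_max = lambda_max),
            class = "infectiousness_law")
}

#' @export
print.infectiousness_law <- function(x, ...) {
  cat(sprintf("<infectiousness_law %s, lambda_max = %g, E[T_I] = %g>\n",
              x$kind, x$lambda_max, law_mean(x$duration)))
  invisible(x)
}

#' Mean infectiousness curve
#'
#' `E[lambda(a)]` with the zero-extension convention (`lambda = 0` after
#' recovery), i.e. the conditional curve times `P(T_I > a)`.
#'
#' @param inf An `infectiousness_law`.
#' @param a Vector of times since infection.
#' @param conditional If `TRUE`, return `E[lambda(a) | T_I > a]` instead.
#' @return Numeric vector of rates.
#' @export
mean_infectiousness <- function(inf, a, conditional = FALSE) {
  stopifnot(inherits(inf, "infectiousness_law"))
  base <- if (inf$kind == "constant") rep(inf$rate, length(a)) else
    inf$shape_fun(a)
  if (conditional) base else base * law_survival(inf$duration, a)
}

#' Basic reproduction number
#'
#' The expected number of secondary cases of one infected individual in a
#' fully susceptible population: the integral of the mean infectiousness
#' curve `E[lambda(a)]` over all ages.
#'
#' @param inf An `infectiousness_law`.
#' @param rel_tol Quadrature tolerance.
#' @return A single non-negative number.
#' @export
basic_reproduction_number <- function(inf, rel_tol = 1e-10) {
  stopifnot(inherits(inf, "infectiousness_law"))
  up <- law_upper(inf$duration, 1e-13)
  if (!is.finite(up)) {
    # an infinite infectious period with non-vanishing transmission has no
    # finite case count
    probe <- mean_infectiousness(inf, c(1e6, 1e8))
    if (any(probe > 1e-12)) {
      stop("mean infectiousness curve is not integrable", call. = FALSE)
    }
    up <- 1e6
  }
  if (inf$lambda_max == 0) return(0)
  val <- stats::integrate(function(a) mean_infectiousness(inf, a), 0, up,
                          rel.tol = rel_tol, abs.tol = rel_tol,
                          subdivisions = 2000L, stop.on.error = FALSE)
  val$value
}

# Multiply the transmission rate by a constant (used by the R0 override).
rescale_infectiousness <- function(inf, c) {
  stopifnot(inherits(inf, "infectiousness_law"), is.finite(c), c >= 0)
  if (inf$kind == "constant") {
    infectiousness_law("constant", duration = inf$duration,
                       rate = inf$rate * c)
  } else {
    f <- inf$shape_fun
    infectiousness_law("shape", duration = inf$duration,
                       shape_fun = function(a) c * f(a),
                       lambda_max = inf$lambda_max * c)
  }
}
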