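#' Duration laws
#'
#' A `duration_law` describes the distribution of a non-negative random
#' duration: an infectious period, the interval between two booster doses of
#' a recurrently vaccinated individual, or the length of the fully immune
#' window after recovery.  The object carries closures for the density,
#' survival function, quantile function and sampler, so that every consumer
#' (hazards, stationary susceptibility, the Volterra solver, the simulator)
#' evaluates the same distribution.
#'
#' Supported families:
#' * `"exponential"` with `rate`;
#' * `"gamma"` with `shape` and `scale`;
#' * `"uniform"` on `[min, max]`;
#' * `"point"`: a point mass at `value` (no density);
#' * `"twopoint"`: a mixture of point masses at `value1` (probability
#'   `prob`) and `value2`;
#' * `"infinite"`: the sentinel "never happens" law (used to switch
#'   vaccination off and to recover SIR/SIS/SIRS dynamics).
#'
#' Any family accepts a non-negative `shift`, giving the law of `shift + T`.
#'
#' @param family Family name, see Details.
#' @param ... Family parameters (`rate`; `shape`, `scale`; `min`, `max`;
#'   `value`).
#' @param shift Non-negative time added to the base variable.
#' @return An object of class `duration_law`.
#' @examples
#' tv <- duration_law("gamma", shape = 4, scale = 45)
#' law_mean(tv)
#' law_survival(tv, c(0, 90, 360))
#' @export
duration_law <- function(family = c("exponential", "gamma", "uniform",
                                    "point", "twopoint", "infinite"),
                         ..., shift = 0) {
  family <- match.arg(family)
  pars <- list(...)
  stopifnot(is.numeric(shift), length(shift) == 1L, shift >= 0)
  need <- function(nm) {
    if (is.null(pars[[nm]])) {
      stop(sprintf("duration_law('%s') requires parameter '%s'", family, nm),
           call. = FALSE)
    }
    p <- pars[[nm]]
    stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
    p
  }
  base <- switch(family,
    exponential = {
      rate <- need("rate")
      stopifnot(rate > 0)
      list(d = function(a) stats::dexp(a, rate),
           s = function(a) stats::pexp(a, rate, lower.tail = FALSE),
           q = function(p) stats::qexp(p, rate),
           r = function(n) stats::rexp(n, rate),
           mean = 1 / rate, pars = list(rate = rate), has_density = TRUE)
    },
    gamma = {
      shape <- need("shape"); scale <- need("scale")
      stopifnot(shape > 0, scale > 0)
      list(d = function(a) stats::dgamma(a, shape, scale = scale),
           s = function(a) stats::pgamma(a, shape, scale = scale,
                                         lower.tail = FALSE),
           q = function(p) stats::qgamma(p, shape, scale = scale),
           r = function(n) stats::rgamma(n, shape, scale = scale),
           mean = shape * scale, pars = list(shape = shape, scale = scale),
           has_density = TRUE)
    },
    uniform = {
      mn <- need("min"); mx <- need("max")
      stopifnot(mn >= 0, mx > mn)
      list(d = function(a) stats::dunif(a, mn, mx),
           s = function(a) stats::punif(a, mn, mx, lower.tail = FALSE),
           q = function(p) stats::qunif(p, mn, mx),
           r = function(n) stats::runif(n, mn, mx),
           mean = (mn + mx) / 2, pars = list(min = mn, max = mx),
           has_density = TRUE)
    },
    point = {
      v <- need("value")
      stopifnot(v >= 0)
      list(d = NULL,
           s = function(a) as.numeric(a < v),
           q = function(p) rep(v, length(p)),
           r = function(n) rep(v, n),
           mean = v, pars = list(value = v), has_density = FALSE)
    },
    twopoint = {
      v1 <- need("value1"); v2 <- need("value2"); pr <- need("prob")
      stopifnot(v1 >= 0, v2 >= v1, pr > 0, pr < 1)
      list(d = NULL,
           s = function(a) pr * (a < v1) + (1 - pr) * (a < v2),
           q = function(p) ifelse(p <= pr, v1, v2),
           r = function(n) ifelse(stats::runif(n) < pr, v1, v2),
           mean = pr * v1 + (1 - pr) * v2,
           pars = list(value1 = v1, value2 = v2, prob = pr),
           has_density = FALSE)
    },
    infinite = {
      list(d = NULL,
           s = function(a) rep(1, length(a)),
           q = function(p) rep(Inf, length(p)),
           r = function(n) rep(Inf, n),
           mean = Inf, pars = list(), has_density = FALSE)
    })

  law <- list(
    family = family,
    pars = base$pars,
    shift = shift,
    mean = base$mean + if (is.finite(base$mean)) shift else 0,
    has_density = base$has_density,
    is_point_mass = family == "point",
    is_infinite = family == "infinite",
    density = if (base$has_density) {
      function(a) ifelse(a >= shift, base$d(pmax(a - shift, 0)), 0)
    } else NULL,
    survival = function(a) ifelse(a < shift, 1, base$s(pmax(a - shift, 0))),
    quantile = function(p) shift + base$q(p),
    sample = function(n) shift + base$r(n)
  )
  structure(law, class = "duration_law")
}

#' @export
print.duration_law <- function(x, ...) {
  p <- paste(names(x$pars), unlist(x$pars), sep = " = ", collapse = ", ")
  cat(sprintf("<duration_law %s(%s)%s>  mean = %g\n", x$family, p,
              if (x$shift > 0) sprintf(" + %g", x$shift) else "", x$mean))
  invisible(x)
}

#' @rdname duration_law
#' @param law A `duration_law`.
#' @param a Vector of non-negative times.
#' @export
law_density <- function(law, a) {
  stopifnot(inherits(law, "duration_law"))
  if (!law$has_density) {
    stop("this duration law has no density", call. = FALSE)
  }
  law$density(a)
}

#' @rdname duration_law
#' @export
law_survival <- function(law, a) {
  stopifnot(inherits(law, "duration_law"))
  law$survival(a)
}

#' @rdname duration_law
#' @param p Vector of probabilities.
#' @export
law_quantile <- function(law, p) {
  stopifnot(inherits(law, "duration_law"))
  law$quantile(p)
}

#' @rdname duration_law
#' @export
law_mean <- function(law) {
  stopifnot(inherits(law, "duration_law"))
  law$mean
}

#' @rdname duration_law
#' @param n Number of draws.
#' @export
law_sample <- function(law, n) {
  stopifnot(inherits(law, "duration_law"))
  law$sample(n)
}

#' Age-dependent event hazard of a duration law
#'
#' The hazard at class age `a` is `density(a) / survival(a)`: the
#' instantaneous recovery rate of an infected individual (for the infectious
#' period law) or the vaccination rate of a susceptible individual (for the
#' booster-interval law).
#'
#' Point-mass laws have no hazard representation; their events are scheduled
#' deterministically by the simulator and solver, and asking for a hazard is
#' an error.
#'
#' @param law A `duration_law` with a density.
#' @param a Vector of ages inside the support of the law.
#' @return The hazard, a non-negative rate vector.
#' @examples
#' hazard(duration_law("exponential", rate = 0.2), c(1, 5, 10)) # constant
#' @export
hazard <- function(law, a) {
  stopifnot(inherits(law, "duration_law"))
  if (law$is_point_mass) {
    stop(paste("point-mass durations have no hazard;",
               "schedule the event at its deterministic time instead"),
         call. = FALSE)
  }
  if (!law$has_density) {
    stop("this duration law has no density, so no hazard", call. = FALSE)
  }
  s <- law$survival(a)
  if (any(s <= 0)) {
    stop("hazard requested beyond the support of the law (survival = 0)",
         call. = FALSE)
  }
  law$density(a) / s
}

#' Rescale a duration law
#'
#' Returns the law of `c * T`.  Used by the fair-allocation analysis, where
#' the booster interval of each group is the common interval scaled by the
#' dose share that the group receives.
#'
#' @param law A `duration_law`.
#' @param c Positive scale factor; `Inf` yields the infinite sentinel law.
#' @return A `duration_law`.
#' @export
law_scale <- function(law, c) {
  stopifnot(inherits(law, "duration_law"), is.numeric(c), length(c) == 1L,
            c > 0)
  if (is.infinite(c) || law$is_infinite) {
    return(duration_law("infinite"))
  }
  sh <- law$shift * c
  switch(law$family,
    exponential = duration_law("exponential", rate = law$pars$rate / c,
                               shift = sh),
    gamma = duration_law("gamma", shape = law$pars$shape,
                         scale = law$pars$scale * c, shift = sh),
    uniform = duration_law("uniform", min = law$pars$min * c,
                           max = law$pars$max * c, shift = sh),
    point = duration_law("point", value = law$pars$value * c, shift = sh),
    twopoint = duration_law("twopoint", value1 = law$pars$value1 * c,
                            value2 = law$pars$value2 * c,
                            prob = law$pars$prob, shift = sh),
    stop("cannot rescale this family"))
}

# Upper truncation point used for age integrals: the 1 - eps quantile.
law_upper <- function(law, eps = 1e-8) {
  if (law$is_infinite) return(Inf)
  law$quantile(1 - eps)
}

# Sample conditioned on T > age, by inverse-CDF restriction (exact).
law_sample_conditional <- function(law, age, eps = 1e-12) {
  stopifnot(inherits(law, "duration_law"), all(age >= 0))
  n <- length(age)
  if (law$is_infinite) return(rep(Inf, n))
  s <- law$survival(age)
  if (any(s <= eps)) {
    bad <- age[which(s <= eps)[1]]
    stop(sprintf("cannot condition on T > %g: age is beyond the support", bad),
         call. = FALSE)
  }
  if (law$is_point_mass) return(rep(law$pars$value + law$shift, n))
  u <- stats::runif(n)
  law$quantile(1 - u * s)
}
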