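#' Susceptibility laws
#'
#' A `susceptibility_law` is a distribution over random susceptibility
#' curves: after every recovery or vaccination an individual draws a
#' non-decreasing function `sigma` on `[0, 1]`, and `sigma(a)` is its
#' probability of infection upon infectious contact at class age `a`
#' (time since the resetting event).  Waning immunity is the increase of
#' `sigma` with age; `sigma(0)` is typically 0 (full protection right after
#' boosting).
#'
#' Three kinds are supported:
#' * `"deterministic"`: a single fixed curve, e.g. [sigma_gamma_cdf()] with
#'   its plateau-then-loss shape, or [sigma_constant()];
#' * `"step"`: full protection for a random window `T_R` drawn from a
#'   [duration_law()], then full susceptibility (`sigma = 1(a >= T_R)`);
#'   with `T_R` exponential this recovers SIRS dynamics, `T_R = 0` SIS,
#'   `T_R = Inf` SIR;
#' * `"panel"`: a finite panel of curves materialized once from a seeded
#'   sampler and reused in every evaluation, so that functionals of the law
#'   are smooth in their arguments (common random numbers).
#'
#' @param kind `"deterministic"`, `"step"` or `"panel"`.
#' @param fn Vectorized non-decreasing function into `[0, 1]`
#'   (`kind = "deterministic"`).
#' @param recovery A [duration_law()] for the immune window `T_R`
#'   (`kind = "step"`).
#' @param sampler Function of a single index `k` returning a curve function
#'   (`kind = "panel"`).
#' @param n_panel Panel size.
#' @param panel_seed Seed used to materialize the panel.
#' @return An object of class `susceptibility_law`.
#' @examples
#' susceptibility_law("step", recovery = duration_law("exponential", rate = 1))
#' @export
susceptibility_law <- function(kind = c("deterministic", "step", "panel"),
                               fn = NULL, recovery = NULL, sampler = NULL,
                               n_panel = 512L, panel_seed = 1L) {
  kind <- match.arg(kind)
  curves <- NULL
  if (kind == "deterministic") {
    stopifnot(is.function(fn))
  } else if (kind == "step") {
    stopifnot(inherits(recovery, "duration_law"))
  } else {
    stopifnot(is.function(sampler), n_panel >= 1L)
    curves <- local({
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(panel_seed)
      lapply(seq_len(n_panel), sampler)
    })
  }
  structure(list(kind = kind, fn = fn, recovery = recovery,
                 curves = curves, n_panel = n_panel,
                 panel_seed = panel_seed),
            class = "susceptibility_law")
}

#' @export
print.susceptibility_law <- function(x, ...) {
  extra <- switch(x$kind,
    step = sprintf(", E[T_R] = %g", law_mean(x$recovery)),
    panel = sprintf(", %d curves", x$n_panel),
    "")
  cat(sprintf("<susceptibility_law %s%s>\n", x$kind, extra))
  invisible(x)
}

#' @describeIn susceptibility_law Constant susceptibility `value`; with
#'   `value = 1` infection confers no immunity (SIS), with `value = 0` it
#'   confers permanent sterilizing immunity.
#' @param value Constant in `[0, 1]`.
#' @export
sigma_constant <- function(value) {
  stopifnot(value >= 0, value <= 1)
  force(value)
  susceptibility_law("deterministic", fn = function(a) rep(value, length(a)))
}

#' @describeIn susceptibility_law Deterministic curve
#'   `sigma(a) = P(Gamma(shape, scale) <= a)`: immunity plateaus near full
#'   protection and is then lost around age `shape * scale`, more sharply
#'   for larger `shape`.
#' @param shape,scale Gamma parameters of the waning profile.
#' @export
sigma_gamma_cdf <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  susceptibility_law("deterministic",
                     fn = function(a) stats::pgamma(a, shape, scale = scale))
}

#' Mean susceptibility curve
#'
#' `E[sigma(a)]`, the expected susceptibility of an individual a time `a`
#' after its last recovery or vaccination, absent any exposure conditioning.
#' For a step law this is `P(T_R <= a)`.
#'
#' @param sus A `susceptibility_law`.
#' @param a Vector of class ages.
#' @return Numeric vector in `[0, 1]`.
#' @export
mean_susceptibility <- function(sus, a) {
  stopifnot(inherits(sus, "susceptibility_law"))
  switch(sus$kind,
    deterministic = sus$fn(a),
    step = 1 - law_survival(sus$recovery, a),
    panel = {
      m <- vapply(sus$curves, function(f) f(a), numeric(length(a)))
      if (length(a) == 1L) mean(m) else rowMeans(matrix(m, nrow = length(a)))
    })
}

# Long-age limit of E[sigma(a)]; 1 under full waning.
sigma_limit <- function(sus) {
  mean_susceptibility(sus, 1e9)
}

#' Mean cumulative susceptibility
#'
#' `Phi(t) = integral of E[sigma(a)] over [0, t]`, the expected cumulated
#' susceptibility since the last immunizing event.  `Phi` is convex and
#' non-decreasing because every susceptibility curve is non-decreasing; its
#' convexity is what makes evenly spaced boosters optimal.
#'
#' @param sus A `susceptibility_law`.
#' @param t Vector of non-negative times.
#' @return `Phi(t)`, same length as `t`.
#' @export
mean_cumulative_susceptibility <- function(sus, t) {
  stopifnot(inherits(sus, "susceptibility_law"), all(t >= 0))
  one <- function(tt) {
    if (tt == 0) return(0)
    stats::integrate(function(a) mean_susceptibility(sus, a), 0, tt,
                     rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 2000L, stop.on.error = FALSE)$value
  }
  vapply(t, one, numeric(1))
}

#' Stationary susceptibility under recurrent vaccination
#'
#' The mean susceptibility of the population at the disease-free
#' equilibrium, when boosters recur with inter-dose law `vac`:
#' `Sigma = E[Phi(T_V)] / E[T_V] = integral E[sigma(a)] P(T_V > a) da /
#' E[T_V]`.  The disease can become endemic if and only if
#' `R0 * Sigma > 1`, so `1 / Sigma` is the endemic threshold.
#'
#' For the infinite sentinel law (no vaccination) the long-age limit of
#' `E[sigma(a)]` is returned with a warning: with immunity fully waning this
#' is 1, the unvaccinated value.
#'
#' @param sus A [susceptibility_law()].
#' @param vac A [duration_law()] for the booster interval `T_V`.
#' @return A number in `[0, 1]`.
#' @examples
#' sus <- susceptibility_law("step", recovery = duration_law("point", value = 1))
#' stationary_susceptibility(sus, duration_law("point", value = 2)) # 0.5
#' @export
stationary_susceptibility <- function(sus, vac) {
  stopifnot(inherits(sus, "susceptibility_law"),
            inherits(vac, "duration_law"))
  if (vac$is_infinite) {
    warning(paste("infinite-mean vaccination law: returning the large-age",
                  "limit of the mean susceptibility"), call. = FALSE)
    return(sigma_limit(sus))
  }
  m <- law_mean(vac)
  stopifnot(is.finite(m), m > 0)
  up <- law_upper(vac, 1e-13)
  num <- stats::integrate(
    function(a) mean_susceptibility(sus, a) * law_survival(vac, a),
    0, up, rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 2000L,
    stop.on.error = FALSE)$value
  min(max(num / m, 0), 1)
}

#' Compare two booster-interval laws of equal cost
#'
#' With the number of doses per unit time fixed (`1 / E[T_V]`), strategies
#' are compared by their stationary susceptibility `Sigma`.  By Jensen's
#' inequality applied to the convex `Phi`, the point mass at the common mean
#' (perfectly regular boosting) is never worse; more generally, a law that
#' is smaller in convex order gives a smaller `Sigma`.
#'
#' @param vac1,vac2 Two [duration_law()]s with the same mean.
#' @param sus A [susceptibility_law()].
#' @param tol Relative tolerance for the equal-mean check.
#' @return A one-row tibble with `sigma1`, `sigma2`, `delta = sigma1 -
#'   sigma2` and its `sign`.
#' @export
convex_order_compare <- function(vac1, vac2, sus, tol = 1e-8) {
  stopifnot(inherits(vac1, "duration_law"), inherits(vac2, "duration_law"))
  m1 <- law_mean(vac1); m2 <- law_mean(vac2)
  if (!is.finite(m1) || !is.finite(m2) ||
      abs(m1 - m2) > tol * max(m1, m2)) {
    stop(paste("the comparison requires equal means (equal dose budgets);",
               sprintf("got E[T_V] = %g and %g", m1, m2)), call. = FALSE)
  }
  s1 <- stationary_susceptibility(sus, vac1)
  s2 <- stationary_susceptibility(sus, vac2)
  tibble::tibble(mean = m1, sigma1 = s1, sigma2 = s2, delta = s1 - s2,
                 sign = sign(s1 - s2))
}
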