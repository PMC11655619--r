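#' Full model specification
#'
#' Bundles everything that defines the homogeneous epidemic model: the
#' infectiousness law, the susceptibility law, the booster-interval law, and
#' the initial condition.  The epidemic is assumed to have been circulating
#' (or vaccination running) long enough that every individual has a class
#' age at time 0: a fraction `i0` is infected with ages drawn from the
#' density `h_i`, the rest susceptible with ages drawn from `h_s`.
#'
#' `h_i` and `h_s` are given as [duration_law()]s and their densities are
#' used as age densities (a point mass puts the whole cohort at one age).
#'
#' @param infectiousness An [infectiousness_law()].
#' @param susceptibility A [susceptibility_law()].
#' @param vaccination A [duration_law()] for the booster interval; the
#'   infinite sentinel switches vaccination off.
#' @param i0 Initial infected fraction, in (0, 1).
#' @param h_i,h_s Initial class-age laws of infected / susceptible
#'   individuals.  Defaults: the stationary [residual_law()] of the
#'   infectious period and of the booster interval (exponential with mean
#'   1 without vaccination).
#' @param r0 Optional target basic reproduction number; the transmission
#'   rate is rescaled so that the spec's `R0` equals it.  Rescaling leaves
#'   the stationary susceptibility untouched.
#' @return An object of class `model_spec`.
#' @examples
#' spec <- default_model_spec(r0 = 3)
#' spec$r0
#' endemic_threshold(spec)
#' @export
model_spec <- function(infectiousness, susceptibility, vaccination,
                       i0 = 0.1, h_i = NULL, h_s = NULL, r0 = NULL) {
  stopifnot(inherits(infectiousness, "infectiousness_law"),
            inherits(susceptibility, "susceptibility_law"),
            inherits(vaccination, "duration_law"),
            is.numeric(i0), length(i0) == 1L, i0 > 0, i0 < 1)
  if (is.null(h_i)) {
    h_i <- residual_law(infectiousness$duration)
  }
  if (is.null(h_s)) {
    h_s <- if (vaccination$is_infinite) {
      duration_law("exponential", rate = 1)
    } else {
      residual_law(vaccination)
    }
  }
  stopifnot(inherits(h_i, "duration_law"), inherits(h_s, "duration_law"))
  if (h_i$is_infinite || h_s$is_infinite) {
    stop("initial age laws must be proper distributions", call. = FALSE)
  }
  if (!is.null(r0)) {
    stopifnot(is.numeric(r0), length(r0) == 1L, r0 > 0)
    nat <- basic_reproduction_number(infectiousness)
    if (nat <= 0) stop("cannot rescale a zero infectiousness law",
                       call. = FALSE)
    infectiousness <- rescale_infectiousness(infectiousness, r0 / nat)
  }
  structure(list(infectiousness = infectiousness,
                 susceptibility = susceptibility,
                 vaccination = vaccination,
                 i0 = i0, h_i = h_i, h_s = h_s,
                 r0 = basic_reproduction_number(infectiousness)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat(sprintf("  R0     : %.4g\n", x$r0))
  cat(sprintf("  T_I    : %s (mean %.4g)\n", x$infectiousness$duration$family,
              law_mean(x$infectiousness$duration)))
  cat(sprintf("  sigma  : %s\n", x$susceptibility$kind))
  cat(sprintf("  T_V    : %s (mean %.4g)\n", x$vaccination$family,
              law_mean(x$vaccination)))
  cat(sprintf("  I_0    : %g\n", x$i0))
  invisible(x)
}

#' Replace the target reproduction number of a spec
#'
#' @param spec A [model_spec()].
#' @param r0 New basic reproduction number.
#' @return A `model_spec` with rescaled transmission.
#' @export
set_r0 <- function(spec, r0) {
  stopifnot(inherits(spec, "model_spec"))
  model_spec(spec$infectiousness, spec$susceptibility, spec$vaccination,
             i0 = spec$i0, h_i = spec$h_i, h_s = spec$h_s, r0 = r0)
}

#' Reference model specification
#'
#' The package's documented default parameterization, in days: a constant
#' transmission rate over a Gamma(2, 3.5) infectious period (mean one week);
#' a Gamma-CDF susceptibility curve with shape 4 and scale 45 (protection
#' plateaus and is then lost around six months); Gamma(4, 45) booster
#' intervals (mean six months, regular but not clockwork); 10% initially
#' infected.
#'
#' @param r0 Basic reproduction number.
#' @param i0 Initial infected fraction.
#' @param theta_sigma Scale of the susceptibility waning profile (days).
#' @return A [model_spec()].
#' @export
default_model_spec <- function(r0 = 3, i0 = 0.1, theta_sigma = 45) {
  inf <- infectiousness_law("constant", rate = 1,
                            duration = duration_law("gamma", shape = 2,
                                                    scale = 3.5))
  model_spec(inf,
             sigma_gamma_cdf(shape = 4, scale = theta_sigma),
             duration_law("gamma", shape = 4, scale = 45),
             i0 = i0, r0 = r0)
}

#' Endemic threshold of a model specification
#'
#' The value `1 / Sigma` of the basic reproduction number above which an
#' endemic equilibrium exists, `Sigma` being the stationary susceptibility
#' of the disease-free vaccination renewal process.  `+Inf` when vaccination
#' maintains zero susceptibility (permanent sterilizing immunity).
#'
#' @param spec A [model_spec()].
#' @return A number `>= 1`, possibly `Inf`.
#' @export
endemic_threshold <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  sig <- stationary_susceptibility(spec$susceptibility, spec$vaccination)
  if (sig <= 0) Inf else 1 / sig
}
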