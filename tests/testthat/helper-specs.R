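# Shared model builders for the test suite.  Time unit: the mean
# infectious period (1).

# Classical SIRS limit: constant transmission, exponential infectious
# period, full immunity for an exponential window, no vaccination.
sirs_spec <- function(beta = 2, gam = 1, om = 0.5, i0 = 0.1) {
  model_spec(
    infectiousness_law("constant", rate = beta,
                       duration = duration_law("exponential", rate = gam)),
    susceptibility_law("step",
                       recovery = duration_law("exponential", rate = om)),
    duration_law("infinite"), i0 = i0,
    h_i = duration_law("exponential", rate = gam),
    h_s = duration_law("point", value = 0))
}

# SIS limit: no immunity at all, no vaccination.
sis_spec <- function(r0 = 2, i0 = 0.1) {
  model_spec(
    infectiousness_law("constant", rate = r0,
                       duration = duration_law("exponential", rate = 1)),
    sigma_constant(1), duration_law("infinite"), i0 = i0,
    h_s = duration_law("exponential", rate = 1))
}

# Vaccinated model with a smooth plateau-then-loss susceptibility curve.
waning_spec <- function(r0 = 3, theta_sigma = 1, i0 = 0.1) {
  model_spec(
    infectiousness_law("constant", rate = 1,
                       duration = duration_law("exponential", rate = 1)),
    sigma_gamma_cdf(4, theta_sigma),
    duration_law("gamma", shape = 4, scale = 1.5),
    i0 = i0, r0 = r0)
}

# Vaccinated model with a random full-immunity window (step curve).
step_vax_spec <- function(r0 = 2, om = 1, i0 = 0.1) {
  model_spec(
    infectiousness_law("constant", rate = 1,
                       duration = duration_law("exponential", rate = 1)),
    susceptibility_law("step",
                       recovery = duration_law("exponential", rate = om)),
    duration_law("gamma", shape = 2, scale = 2),
    i0 = i0, r0 = r0)
}

# Random valid spec generator used by the conservation property tests.
random_spec <- function() {
  ti <- duration_law("gamma", shape = stats::runif(1, 1.5, 3),
                     scale = stats::runif(1, 0.4, 0.8))
  sus <- if (stats::runif(1) < 0.5) {
    sigma_gamma_cdf(stats::runif(1, 2, 6), stats::runif(1, 0.3, 1.5))
  } else {
    susceptibility_law("step",
                       recovery = duration_law("exponential",
                                               rate = stats::runif(1, 0.5, 2)))
  }
  vac <- switch(sample.int(3, 1),
    duration_law("gamma", shape = stats::runif(1, 2, 5),
                 scale = stats::runif(1, 0.5, 1.5)),
    duration_law("uniform", min = stats::runif(1, 0.5, 1),
                 max = stats::runif(1, 3, 6)),
    duration_law("point", value = stats::runif(1, 2, 5)))
  model_spec(infectiousness_law("constant", rate = 1, duration = ti),
             sus, vac, i0 = stats::runif(1, 0.05, 0.3),
             r0 = stats::runif(1, 1.5, 4))
}

# Independent SIRS ODE oracle (deSolve), on the same state convention as
# sirs_spec(): initial susceptibles all have age 0 (fully immune).
sirs_ode_oracle <- function(beta, gam, om, i0, times, s0 = 0, r0c = NULL) {
  if (is.null(r0c)) r0c <- 1 - i0 - s0
  f <- function(t, y, p) {
    with(as.list(c(y, p)), {
      list(c(om * R - beta * S * I, beta * S * I - gam * I,
             gam * I - om * R))
    })
  }
  out <- deSolve::ode(c(S = s0, I = i0, R = r0c), times = times, func = f,
                      parms = c(beta = beta, gam = gam, om = om),
                      rtol = 1e-10, atol = 1e-12)
  tibble::tibble(t = out[, "time"], S = out[, "S"], I = out[, "I"],
                 R = out[, "R"])
}
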