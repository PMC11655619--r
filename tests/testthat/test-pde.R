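test_that("total immunity shuts off reinfection and prevalence decays", {
  spec <- model_spec(
    infectiousness_law("constant", rate = 2,
                       duration = duration_law("exponential", rate = 1)),
    sigma_constant(0), duration_law("infinite"), i0 = 0.4,
    h_i = duration_law("exponential", rate = 1),
    h_s = duration_law("exponential", rate = 1))
  sol <- solve_volterra(spec, dt = 0.02, tmax = 20)
  expect_lt(max(sol$tab$x), 1e-12)
  expect_lt(utils::tail(sol$tab$prevalence, 1), 1e-6)
  expect_lt(sol$mass_drift, 1e-3)
})

test_that("the SIRS reduction matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  spec <- sirs_spec(beta = 2, gam = 1, om = 0.5)
  sol <- solve_volterra(spec, dt = 0.02, tmax = 40)
  ode <- sirs_ode_oracle(2, 1, 0.5, 0.1, times = seq(0, 40, 0.02))
  expect_lt(max(abs(ode$I - sol$tab$prevalence)), 1e-2)
})

test_that("solutions conserve mass and respect the a-priori bound", {
  sol <- solve_volterra(waning_spec(r0 = 3), dt = 0.02, tmax = 40)
  expect_lt(sol$mass_drift, 1e-3)
  expect_true(all(sol$tab$x <= sol$tab$Lambda * (1 + 1e-6) + 1e-10))
  expect_true(all(sol$tab$prevalence >= 0))
  expect_true(all(sol$tab$susceptible_mass >= 0))
  lmax <- waning_spec(r0 = 3)$infectiousness$lambda_max
  ok <- sol$tab$t * lmax < 700
  expect_true(all(sol$tab$Lambda[ok] <=
                    0.1 * lmax * exp(lmax * sol$tab$t[ok]) + 1e-9))
})

test_that("halving the step shrinks the solution error", {
  spec <- step_vax_spec(r0 = 2)
  fine <- solve_volterra(spec, dt = 0.005, tmax = 15)
  sub <- function(sol, dt) {
    sol$tab$prevalence[as.integer(round(seq(0, 15, 0.1) / dt)) + 1]
  }
  ref <- sub(fine, 0.005)
  e1 <- max(abs(sub(solve_volterra(spec, dt = 0.04, tmax = 15), 0.04) - ref))
  e2 <- max(abs(sub(solve_volterra(spec, dt = 0.02, tmax = 15), 0.02) - ref))
  expect_lt(e2, e1)
  expect_lt(e2, 0.6 * e1 + 1e-6)
})

test_that("exposure conditioning: closed forms and a Monte Carlo oracle", {
  # no exposure: plain mean curve
  sus <- susceptibility_law("step",
                            recovery = duration_law("exponential", rate = 1))
  expect_equal(exposure_weighted_susceptibility(sus, 0, 2),
               mean_susceptibility(sus, 2), tolerance = 1e-10)
  # deterministic curve: the bias vanishes identically
  det <- sigma_gamma_cdf(4, 1)
  expect_equal(exposure_weighted_susceptibility(det, 1.7, 2.3),
               mean_susceptibility(det, 2.3), tolerance = 1e-12)
  # random immune window under constant exposure vs brute-force MC
  set.seed(5)
  L <- 1; a <- 2
  got <- exposure_weighted_susceptibility(sus, L, a, n_nodes = 4096L)
  tr <- rexp(1e6, 1)
  w <- exp(-L * pmax(a - tr, 0))
  mc <- sum((tr <= a) * w) / sum(w)
  se <- sd((tr <= a) * w - mc * w) / mean(w) / sqrt(1e6)
  expect_lt(abs(got - mc), 4 * se + 1e-6)
})

test_that("age densities reconstruct the initial condition and boundary", {
  spec <- waning_spec(r0 = 3)
  sol <- solve_volterra(spec, dt = 0.02, tmax = 10,
                        density_times = c(0, 5, 10))
  d <- reconstruct_age_densities(sol, amax = 6)
  expect_true(all(d$I >= 0) && all(d$S >= 0))
  # initial cohorts are equal-mass atoms, so compare binned masses rather
  # than pointwise density values
  d0 <- d[d$t == 0, ]
  bins <- seq(0.5, 5.5, by = 0.5)
  for (k in seq_len(length(bins) - 1L)) {
    sel <- d0$a >= bins[k] & d0$a < bins[k + 1L]
    mI <- sum(d0$I[sel]) * sol$dt
    mS <- sum(d0$S[sel]) * sol$dt
    oI <- spec$i0 * (law_survival(spec$h_i, bins[k]) -
                       law_survival(spec$h_i, bins[k + 1L]))
    oS <- (1 - spec$i0) * (law_survival(spec$h_s, bins[k]) -
                             law_survival(spec$h_s, bins[k + 1L]))
    expect_equal(mI, oI, tolerance = 0.03)
    expect_equal(mS, oS, tolerance = 0.03)
  }
  # boundary self-consistency: x(t) = Lambda(t) * (conditioned mean
  # susceptibility integral), cached as sigma_bar
  expect_equal(sol$tab$x, sol$tab$Lambda * sol$tab$sigma_bar,
               tolerance = 1e-6)
})

test_that("the two force-of-infection forms agree", {
  spec <- waning_spec(r0 = 2.5)
  sol <- solve_volterra(spec, dt = 0.02, tmax = 5)
  # at t = 0: integral of the conditional mean curve against I(0, a),
  # i.e. i0 * int h_i(b) E[lambda(b)] / S_TI(b) db
  lam0 <- integrate(function(b) {
    spec$i0 * law_density(spec$h_i, b) *
      mean_infectiousness(spec$infectiousness, b) /
      law_survival(spec$infectiousness$duration, b)
  }, 0, law_upper(spec$h_i, 1e-10), rel.tol = 1e-10)$value
  expect_equal(force_of_infection(sol, 0), lam0, tolerance = 1e-3)
  expect_error(force_of_infection(sol, 99), "horizon")
})

test_that("prevalence crosses the endemic threshold with R0", {
  spec <- step_vax_spec(r0 = 1)
  thr <- endemic_threshold(spec)
  lo <- solve_volterra(set_r0(spec, 0.8 * thr), dt = 0.02, tmax = 150)
  hi <- solve_volterra(set_r0(spec, 1.3 * thr), dt = 0.02, tmax = 150)
  expect_lt(utils::tail(lo$tab$prevalence, 1), 1e-5)
  expect_gt(utils::tail(hi$tab$prevalence, 1), 1e-3)
})
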