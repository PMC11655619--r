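test_that("basic reproduction number matches quadrature oracles", {
  # constant rate over an exponential period: oracle = integral of
  # beta * exp(-gamma a), analytically beta / gamma
  inf <- infectiousness_law("constant", rate = 0.6,
                            duration = duration_law("exponential",
                                                    rate = 0.2))
  oracle <- integrate(function(a) 0.6 * exp(-0.2 * a), 0, Inf)$value
  expect_equal(basic_reproduction_number(inf), oracle, tolerance = 1e-8)
  expect_equal(basic_reproduction_number(inf), 3, tolerance = 1e-8)

  # zero transmission
  inf0 <- infectiousness_law("constant", rate = 0,
                             duration = duration_law("exponential", rate = 1))
  expect_equal(basic_reproduction_number(inf0), 0)

  # fixed infectious period: beta * d
  infd <- infectiousness_law("constant", rate = 2,
                             duration = duration_law("point", value = 1.5))
  expect_equal(basic_reproduction_number(infd), 3, tolerance = 1e-6)

  # a profiled curve against direct quadrature
  shp <- function(a) a * exp(-a)
  infs <- infectiousness_law("shape", shape_fun = shp,
                             duration = duration_law("gamma", shape = 2,
                                                     scale = 1))
  oracle2 <- integrate(function(a) {
    shp(a) * pgamma(a, 2, scale = 1, lower.tail = FALSE)
  }, 0, 60)$value
  expect_equal(basic_reproduction_number(infs), oracle2, tolerance = 1e-7)
})

test_that("zero-extended mean curve equals conditional curve times survival", {
  inf <- infectiousness_law("constant", rate = 1.3,
                            duration = duration_law("gamma", shape = 2,
                                                    scale = 1))
  a <- seq(0, 8, by = 0.5)
  expect_equal(mean_infectiousness(inf, a),
               mean_infectiousness(inf, a, conditional = TRUE) *
                 law_survival(inf$duration, a))
})

test_that("stationary susceptibility matches analytic and MC oracles", {
  # full immune window of length 1, boosters every 2: (m - r) / m
  sus <- susceptibility_law("step",
                            recovery = duration_law("point", value = 1))
  expect_equal(stationary_susceptibility(sus, duration_law("point", value = 2)),
               0.5, tolerance = 1e-9)

  # no immunity at all: Sigma = 1 whatever the boosters
  expect_equal(stationary_susceptibility(
    sigma_constant(1), duration_law("gamma", shape = 3, scale = 2)), 1,
    tolerance = 1e-8)

  # exponential window vs exponential boosters: MC oracle of
  # E[(T_V - T_R)_+] / E[T_V]; analytically omega / (omega + nu)
  om <- 3; nu <- 1
  sus2 <- susceptibility_law("step",
                             recovery = duration_law("exponential",
                                                     rate = om))
  got <- stationary_susceptibility(sus2,
                                   duration_law("exponential", rate = nu))
  set.seed(99)
  nmc <- 2e5
  w <- pmax(rexp(nmc, nu) - rexp(nmc, om), 0)
  mc <- mean(w) / (1 / nu)
  se <- sd(w) / (1 / nu) / sqrt(nmc)
  expect_lt(abs(got - mc), 4 * se)
  expect_equal(got, om / (om + nu), tolerance = 1e-8)

  # infinite boosters: large-age limit, with a warning
  expect_warning(
    lim <- stationary_susceptibility(sigma_gamma_cdf(4, 1),
                                     duration_law("infinite")),
    "large-age limit")
  expect_equal(lim, 1)
})

test_that("Sigma lies in [0,1] and ignores the transmission scale", {
  set.seed(7)
  for (i in 1:10) {
    spec <- random_spec()
    sig <- 1 / endemic_threshold(spec)
    expect_gte(sig, 0); expect_lte(sig, 1)
    expect_equal(endemic_threshold(set_r0(spec, 7.7)),
                 endemic_threshold(spec), tolerance = 1e-10)
  }
})

test_that("Sigma is non-decreasing in the booster-interval scale", {
  sus <- sigma_gamma_cdf(3, 1)
  base <- duration_law("gamma", shape = 4, scale = 0.5)
  m <- seq(0.25, 4, length.out = 12)
  sig <- vapply(m, function(mm) {
    stationary_susceptibility(sus, law_scale(base, mm))
  }, numeric(1))
  expect_true(all(diff(sig) >= -1e-10))
})

test_that("mean cumulative susceptibility is convex, with known values", {
  expect_equal(mean_cumulative_susceptibility(sigma_gamma_cdf(2, 1), 0), 0)
  expect_equal(mean_cumulative_susceptibility(sigma_constant(1), 3), 3,
               tolerance = 1e-9)
  sus <- susceptibility_law("step",
                            recovery = duration_law("point", value = 1))
  expect_equal(mean_cumulative_susceptibility(sus, 2), 1, tolerance = 1e-9)
  tt <- seq(0, 6, by = 0.25)
  phi <- mean_cumulative_susceptibility(sigma_gamma_cdf(4, 0.8), tt)
  expect_true(all(diff(phi) >= 0))
  expect_true(all(diff(diff(phi)) >= -1e-9))
})

test_that("convex ordering of booster laws orders Sigma", {
  sus <- susceptibility_law("step",
                            recovery = duration_law("point", value = 1))
  cmp <- convex_order_compare(duration_law("point", value = 2),
                              duration_law("exponential", rate = 0.5), sus)
  expect_equal(cmp$sigma1, 0.5, tolerance = 1e-8)
  expect_lte(cmp$sigma1, cmp$sigma2)

  same <- convex_order_compare(duration_law("gamma", shape = 2, scale = 1),
                               duration_law("gamma", shape = 2, scale = 1),
                               sigma_gamma_cdf(3, 1))
  expect_equal(same$delta, 0, tolerance = 1e-12)

  # lower-dispersion gamma is smaller in convex order
  g4 <- duration_law("gamma", shape = 4, scale = 0.5)
  g1 <- duration_law("gamma", shape = 1, scale = 2)
  cmp2 <- convex_order_compare(g4, g1, sigma_gamma_cdf(3, 0.7))
  expect_lte(cmp2$sigma1, cmp2$sigma2)

  expect_error(
    convex_order_compare(duration_law("point", value = 1),
                         duration_law("point", value = 2), sus),
    "equal means")
})
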