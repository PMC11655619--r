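test_that("initialization is seeded, binomial, and age-consistent", {
  spec <- waning_spec(r0 = 3)
  p1 <- ibm_init(spec, 50, seed = 3)
  p2 <- ibm_init(spec, 50, seed = 3)
  expect_identical(p1$state, p2$state)
  expect_identical(p1$sched, p2$sched)

  # infected counts are Binomial(N, i0): mean over replicates within 3
  # binomial standard errors
  set.seed(11)
  reps <- 2000L; n <- 100L
  counts_ibm <- vapply(seq_len(reps), function(r) {
    sum(ibm_init(spec, n)$state)
  }, numeric(1))
  se <- sqrt(n * spec$i0 * (1 - spec$i0) / reps)
  expect_lt(abs(mean(counts_ibm) - n * spec$i0), 3 * se)

  # point-mass initial ages put everyone at age zero
  spec0 <- model_spec(spec$infectiousness, spec$susceptibility,
                      spec$vaccination, i0 = 0.5,
                      h_i = duration_law("point", value = 0),
                      h_s = duration_law("point", value = 0))
  pop <- ibm_init(spec0, 200, seed = 1)
  expect_true(all(pop$tau == 0))
})

test_that("with zero susceptibility the epidemic only burns out", {
  spec <- model_spec(
    infectiousness_law("constant", rate = 2,
                       duration = duration_law("exponential", rate = 1)),
    sigma_constant(0), duration_law("gamma", shape = 2, scale = 1),
    i0 = 0.5, h_i = duration_law("point", value = 0),
    h_s = duration_law("point", value = 0))
  tr <- simulate_ibm(spec, 400, 25, seed = 2)
  expect_equal(utils::tail(tr$incidence, 1), 0)
  expect_equal(utils::tail(tr$prevalence, 1), 0)

  # a single infected individual: exactly one recovery, then vaccinations
  spec1 <- model_spec(spec$infectiousness, sigma_constant(0),
                      duration_law("point", value = 2), i0 = 0.99,
                      h_i = duration_law("point", value = 0),
                      h_s = duration_law("point", value = 0))
  pop <- ibm_init(spec1, 1, seed = 5)
  expect_equal(sum(pop$state), 1L)
  out <- ibm_simulate(pop, 10, event_log = TRUE)
  expect_equal(sum(out$log$event == "recover"), 1L)
  expect_equal(sum(out$log$event == "infect"), 0L)
  expect_gt(sum(out$log$event == "vaccinate"), 0L)
  rec_t <- out$log$t[out$log$event == "recover"]
  expect_true(all(out$log$t[out$log$event == "vaccinate"] > rec_t))
})

test_that("population is conserved and the trajectory is replayable", {
  spec <- step_vax_spec(r0 = 3)
  pop <- ibm_init(spec, 300, seed = 8)
  out <- ibm_simulate(pop, 20)
  expect_equal(length(out$pop$state), 300L)
  expect_true(all(out$pop$state %in% c(0L, 1L)))
  expect_true(all(out$trajectory$prevalence >= 0 &
                    out$trajectory$prevalence <= 1))
  expect_true(all(diff(out$trajectory$incidence) >= 0))
  t1 <- simulate_ibm(spec, 150, 12, replicates = 3, seed = 21)
  t2 <- simulate_ibm(spec, 150, 12, replicates = 3, seed = 21)
  expect_identical(t1, t2)
})

test_that("thinning reproduces the analytic first-infection law", {
  # one permanently infectious individual (constant rate beta) and one
  # fresh susceptible with a deterministic curve: the infection age A of
  # the susceptible has survival exp(-(beta/2) Phi(a))
  beta <- 1.5
  sus <- sigma_gamma_cdf(2, 0.5)
  spec <- model_spec(
    infectiousness_law("constant", rate = beta,
                       duration = duration_law("point", value = 1e7)),
    sus, duration_law("infinite"), i0 = 0.5,
    h_i = duration_law("point", value = 0),
    h_s = duration_law("point", value = 0))
  set.seed(31)
  nrep <- 4000L
  seeds <- sample.int(.Machine$integer.max - 1L, nrep)
  tmax <- 12
  draws <- vapply(seq_len(nrep), function(r) {
    pop <- ibm_init(spec, 2, seed = seeds[r])
    # force the configuration: individual 1 infectious, individual 2 naive
    pop$state <- c(1L, 0L)
    pop$tau <- c(0, 0)
    pop$sched <- c(1e7, Inf)
    pop$lam_val <- c(beta, 0)
    out <- ibm_simulate(pop, tmax, out_dt = tmax, event_log = TRUE)
    inf_t <- out$log$t[out$log$event == "infect" & out$log$individual == 2]
    if (length(inf_t) == 0) Inf else inf_t[1]
  }, numeric(1))
  Lbar <- beta / 2
  cdf <- function(a) {
    1 - exp(-Lbar * mean_cumulative_susceptibility(sus, a))
  }
  obs <- draws[is.finite(draws)]
  expect_gt(length(obs), 100)
  # KS against the conditional-on-observed distribution at 1%
  ks <- suppressWarnings(stats::ks.test(
    obs, function(a) cdf(a) / cdf(tmax)))
  expect_gt(ks$p.value, 0.01)
  # and the censoring mass matches
  pcens <- exp(-Lbar * mean_cumulative_susceptibility(sus, tmax))
  phat <- mean(!is.finite(draws))
  expect_lt(abs(phat - pcens), 4 * sqrt(pcens * (1 - pcens) / nrep) + 1e-3)
})

test_that("the finite population tracks the SIRS ODE oracle", {
  skip_if_not_installed("deSolve")
  spec <- sirs_spec(beta = 2, gam = 1, om = 0.5)
  tr <- simulate_ibm(spec, 3000, 25, replicates = 20, seed = 13,
                     out_dt = 1)
  m <- dplyr::summarise(dplyr::group_by(tr, t),
                        mp = mean(prevalence),
                        se = stats::sd(prevalence) / sqrt(20),
                        .groups = "drop")
  ode <- sirs_ode_oracle(2, 1, 0.5, 0.1, times = seq(0, 25, 1))
  dev <- abs(m$mp - ode$I)
  expect_true(all(dev <= 3.5 * pmax(m$se, 1e-4) + 0.004))
})

test_that("empirical age histograms have the right masses and limit", {
  spec <- waning_spec(r0 = 3)
  pop <- ibm_init(spec, 6000, seed = 17)
  out <- ibm_simulate(pop, 10)
  h <- empirical_age_measures(out$pop, bin_width = 0.5)
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  expect_equal(sum(h$mass[h$compartment == "I"]),
               mean(out$pop$state == 1L), tolerance = 1e-12)

  # two-individual worked example
  toy <- pop; toy$n <- 2; toy$t <- 2
  toy$state <- c(1L, 0L); toy$tau <- c(1.8, 0.3)
  hh <- empirical_age_measures(toy, bin_width = 1)
  expect_equal(hh$mass[hh$compartment == "I" & hh$a_lo == 0], 0.5)
  expect_equal(hh$mass[hh$compartment == "S" & hh$a_lo == 1], 0.5)

  # large-N histogram close to the deterministic age densities
  sol <- solve_volterra(spec, dt = 0.02, tmax = 10, density_times = 10)
  d <- reconstruct_age_densities(sol)
  bw <- 0.5
  for (cc in c("I", "S")) {
    hb <- h[h$compartment == cc & h$a_lo < 4, ]
    dens <- d[[cc]]
    mass_pde <- vapply(hb$a_lo, function(lo) {
      sel <- d$a >= lo & d$a < lo + bw
      sum(dens[sel]) * sol$dt
    }, numeric(1))
    se <- sqrt(pmax(mass_pde, 1e-6) * (1 - pmax(mass_pde, 1e-6)) / 6000)
    expect_true(mean(abs(hb$mass - mass_pde) <= 3 * se + 0.003) > 0.9)
  }
})
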