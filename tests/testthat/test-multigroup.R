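test_that("the two-group contact matrix satisfies its constraints", {
  # well-mixed: all entries 1
  expect_equal(two_group_contact_matrix(0.3, 1), matrix(1, 2, 2))
  # disconnected groups of equal size
  expect_equal(two_group_contact_matrix(0.5, 0), diag(c(2, 2)))
  # equal activity rowwise for random valid parameters
  set.seed(2)
  for (i in 1:20) {
    p1 <- runif(1, 0.1, 0.9); p2 <- 1 - p1
    al <- runif(1, 0, min(1 / p1, 1 / p2))
    G <- two_group_contact_matrix(p1, al)
    expect_equal(as.vector(G %*% c(p1, p2)), c(1, 1), tolerance = 1e-12)
    expect_equal(G[1, 2], G[2, 1])
  }
  expect_error(two_group_contact_matrix(0.25, 3.9), "\\[0, ")
})

test_that("next-generation matrix and its known leading eigenvalues", {
  inf <- infectiousness_law("constant", rate = 1,
                            duration = duration_law("exponential", rate = 1))
  sus <- susceptibility_law("step",
                            recovery = duration_law("exponential", rate = 1))
  vac1 <- duration_law("gamma", shape = 2, scale = 2)
  mk <- function(p1, alpha, v2 = vac1) {
    group_model(c(p1, 1 - p1), two_group_contact_matrix(p1, alpha),
                list(vac1, v2), inf, sus)
  }
  # identical vaccination with equal activity: rho = Sigma, any alpha
  s <- stationary_susceptibility(sus, vac1)
  for (al in c(0.2, 0.7, 1, 1.4)) {
    expect_equal(next_generation(mk(0.4, al))$rho, s, tolerance = 1e-12)
  }
  # well-mixed: rho = p1 Sigma1 + p2 Sigma2
  v2 <- duration_law("gamma", shape = 2, scale = 4)
  ng <- next_generation(mk(0.3, 1, v2), r0 = 3)
  s2 <- stationary_susceptibility(sus, v2)
  expect_equal(ng$rho, 0.3 * s + 0.7 * s2, tolerance = 1e-10)
  expect_identical(ng$endemic, ng$r0_rho > 1)
  # disconnected: analysis refuses, closed form gives max(Sigma1, Sigma2)
  gm0 <- suppressWarnings(mk(0.3, 0, v2))
  expect_error(next_generation(gm0), "irreducible")
  expect_equal(rho_of_alpha(0.3, s, s2, 0), max(s, s2), tolerance = 1e-12)
})

test_that("closed-form rho equals power iteration and is convex decreasing", {
  set.seed(3)
  for (i in 1:20) {
    p1 <- runif(1, 0.1, 0.9); p2 <- 1 - p1
    s1 <- runif(1); s2 <- runif(1)
    alphas <- seq(0, min(1 / p1, 1 / p2), length.out = 100)
    rc <- rho_of_alpha(p1, s1, s2, alphas)
    # dual route at a few points
    for (al in alphas[c(1, 30, 70, 100)]) {
      M <- two_group_contact_matrix(p1, al) *
        matrix(c(p1, p2) * c(s1, s2), 2, 2, byrow = TRUE)
      expect_equal(rho_of_alpha(p1, s1, s2, al),
                   waningvax:::spectral_radius(M), tolerance = 1e-12)
    }
    expect_true(all(diff(rc) <= 1e-12))
    expect_true(all(diff(diff(rc)) >= -1e-10))
    # equal susceptibilities: constant in alpha
    expect_equal(max(abs(rho_of_alpha(p1, s1, s1, alphas) - s1)), 0,
                 tolerance = 1e-12)
  }
})

test_that("critical vaccination fraction: value and threshold identity", {
  # perfect blocking: the classical 1 - 1/R0
  expect_equal(critical_vaccination_fraction(2, 0), 0.5)
  expect_lte(critical_vaccination_fraction(0.9, 0.3), 0)
  expect_error(critical_vaccination_fraction(2, 1), "block")
  set.seed(4)
  for (i in 1:20) {
    r0 <- runif(1, 1.1, 6); sg <- runif(1, 0, 0.9)
    pc <- critical_vaccination_fraction(r0, sg)
    crit <- function(p1) r0 * (1 - (1 - sg) * p1) - 1
    expect_lt(abs(crit(pc)), 1e-10)
    if (pc > 1e-6 && pc < 1 - 1e-6) {
      expect_gt(crit(pc - 1e-6), 0)
      expect_lt(crit(pc + 1e-6), 0)
    }
  }
})

test_that("allocation family preserves the dose budget and its endpoints", {
  T_law <- duration_law("gamma", shape = 4, scale = 45)
  m <- law_mean(T_law)
  p1 <- 0.35; p2 <- 0.65
  al0 <- allocation_laws(T_law, 0, p1)
  expect_equal(al0$m1, m); expect_equal(al0$m2, m)
  alf <- allocation_laws(T_law, 1 / p1, p1)
  expect_true(alf$T2$is_infinite)
  expect_equal(alf$m1, m * p1, tolerance = 1e-12)
  for (b in seq(-1 / p2 + 0.05, 1 / p1 - 0.05, length.out = 17)) {
    al <- allocation_laws(T_law, b, p1)
    expect_equal(p1 / al$m1 + p2 / al$m2, 1 / m, tolerance = 1e-12)
  }
  expect_error(allocation_laws(T_law, 4, p1), "beta")
})

test_that("the even split minimizes the spectral radius", {
  fa <- run_allocation_scan(duration_law("gamma", shape = 4, scale = 45),
                            sigma_gamma_cdf(4, 45), p1 = 0.5,
                            alpha = c(0, 0.25, 0.5, 1), n_beta = 41L)
  for (al in unique(fa$alpha)) {
    sub <- fa[fa$alpha == al, ]
    expect_equal(sub$beta[which.min(sub$rho)], 0, tolerance = 1e-12)
  }
  # symmetric groups: rho symmetric under beta -> -beta
  s <- fa[fa$alpha == 0.5, ]
  expect_equal(s$rho, rev(s$rho), tolerance = 1e-10)
})

test_that("multigroup dynamics collapse to the homogeneous solution", {
  spec <- waning_spec(r0 = 2.5)
  gm <- group_model(c(0.4, 0.6), two_group_contact_matrix(0.4, 1),
                    list(spec$vaccination, spec$vaccination),
                    spec$infectiousness, spec$susceptibility, i0 = spec$i0,
                    h_i = spec$h_i, h_s = spec$h_s)
  mg <- solve_multigroup_volterra(gm, dt = 0.02, tmax = 30)
  ho <- solve_volterra(spec, dt = 0.02, tmax = 30)
  for (l in 1:2) {
    gl <- mg$tab[mg$tab$group == l, ]
    expect_equal(gl$prevalence / gm$p[l], ho$tab$prevalence,
                 tolerance = 1e-8)
  }
  expect_lt(mg$mass_drift, 1e-3)
})

test_that("isolated groups conserve their own masses", {
  spec <- waning_spec(r0 = 2.5)
  gm <- suppressWarnings(
    group_model(c(0.4, 0.6), two_group_contact_matrix(0.4, 0),
                list(spec$vaccination, duration_law("infinite")),
                spec$infectiousness, spec$susceptibility, i0 = spec$i0,
                h_i = spec$h_i, h_s = spec$h_s))
  mg <- solve_multigroup_volterra(gm, dt = 0.02, tmax = 20)
  for (l in 1:2) {
    gl <- mg$tab[mg$tab$group == l, ]
    expect_lt(max(abs(gl$prevalence + gl$susceptible_mass - gm$p[l])), 1e-3)
  }
})

test_that("total prevalence crosses the multigroup threshold R0 rho = 1", {
  inf <- infectiousness_law("constant", rate = 1,
                            duration = duration_law("exponential", rate = 1))
  sus <- susceptibility_law("step",
                            recovery = duration_law("exponential", rate = 1))
  gm <- group_model(c(0.5, 0.5), two_group_contact_matrix(0.5, 0.5),
                    list(duration_law("gamma", shape = 2, scale = 2),
                         duration_law("gamma", shape = 2, scale = 6)),
                    inf, sus, i0 = 0.05)
  rho <- next_generation(gm)$rho
  mk <- function(r0) {
    # E[T_I] = 1 here, so the constant rate is the reproduction number
    group_model(gm$p, gm$contact, gm$vaccination,
                infectiousness_law("constant", rate = r0,
                                   duration = inf$duration),
                sus, i0 = 0.05)
  }
  lo <- solve_multigroup_volterra(mk(0.8 / rho), dt = 0.02, tmax = 120)
  hi <- solve_multigroup_volterra(mk(1.3 / rho), dt = 0.02, tmax = 120)
  expect_lt(utils::tail(lo$total$prevalence, 1), 1e-5)
  expect_gt(utils::tail(hi$total$prevalence, 1), 1e-3)
})
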