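#' Multigroup model with heterogeneous vaccination
#'
#' Extends the homogeneous model to `L` groups with weights `p_l`, a
#' symmetric non-negative irreducible contact matrix `Gamma` and per-group
#' booster-interval laws.  Infectiousness and susceptibility laws are
#' shared across groups (the heterogeneity studied here is in vaccination
#' and contacts).  The derived quantities are the per-group stationary
#' susceptibilities `Sigma_l` and the next-generation matrix
#' `m[l, l'] = p_l' * gamma[l, l'] * Sigma_l'`, whose spectral radius
#' `rho` sets the endemic threshold `R0 * rho > 1`.
#'
#' @param p Group weights, summing to 1.
#' @param contact Symmetric non-negative contact matrix `Gamma`.
#' @param vaccination List of per-group [duration_law()]s.
#' @param infectiousness Shared [infectiousness_law()].
#' @param susceptibility Shared [susceptibility_law()].
#' @param i0 Initial infected fraction (same in every group).
#' @param h_i,h_s Initial age laws shared across groups.
#' @return An object of class `group_model`.
#' @export
group_model <- function(p, contact, vaccination, infectiousness,
                        susceptibility, i0 = 0.1, h_i = NULL, h_s = NULL) {
  L <- length(p)
  stopifnot(L >= 2L, all(p > 0), abs(sum(p) - 1) < 1e-10,
            is.matrix(contact), nrow(contact) == L, ncol(contact) == L,
            all(contact >= 0),
            length(vaccination) == L,
            inherits(infectiousness, "infectiousness_law"),
            inherits(susceptibility, "susceptibility_law"))
  if (max(abs(contact - t(contact))) > 1e-10) {
    stop("the contact matrix must be symmetric", call. = FALSE)
  }
  if (!is_irreducible(contact)) {
    warning(paste("contact matrix is reducible: groups are isolated and",
                  "next-generation analysis is unavailable"), call. = FALSE)
  }
  for (v in vaccination) stopifnot(inherits(v, "duration_law"))
  Sigma <- vapply(vaccination, function(v) {
    if (v$is_infinite) sigma_limit(susceptibility) else
      stationary_susceptibility(susceptibility, v)
  }, numeric(1))
  equal_activity <- max(abs(as.vector(contact %*% p) - 1)) < 1e-8
  structure(list(p = p, contact = contact, vaccination = vaccination,
                 infectiousness = infectiousness,
                 susceptibility = susceptibility,
                 Sigma = Sigma, equal_activity = equal_activity,
                 i0 = i0, h_i = h_i, h_s = h_s),
            class = "group_model")
}

is_irreducible <- function(A) {
  L <- nrow(A)
  reach <- (A > 0) | diag(L)
  for (k in seq_len(L)) reach <- (reach %*% reach) > 0
  all(reach)
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model: %d groups, p = (%s)>\n", length(x$p),
              paste(signif(x$p, 3), collapse = ", ")))
  cat(sprintf("  Sigma = (%s)%s\n", paste(signif(x$Sigma, 4), collapse = ", "),
              if (x$equal_activity) ", equal activity" else ""))
  invisible(x)
}

#' Equal-activity two-group contact matrix
#'
#' Under the constraints that contacts are symmetric and every individual
#' has unit activity (`Gamma p = 1` rowwise), all two-group contact
#' matrices are parametrized by a single assortativity parameter `alpha`:
#' `alpha = 0` disconnects the groups, `alpha = 1` is well-mixed,
#' `alpha > 1` is dissortative, up to `min(1/p1, 1/p2)`.
#'
#' @param p1 Weight of group 1 (group 2 has `1 - p1`).
#' @param alpha Contact parameter.
#' @return A 2x2 matrix.
#' @export
two_group_contact_matrix <- function(p1, alpha) {
  stopifnot(p1 > 0, p1 < 1)
  p2 <- 1 - p1
  amax <- min(1 / p1, 1 / p2)
  if (alpha < 0 || alpha > amax) {
    stop(sprintf("alpha must lie in [0, %g]", amax), call. = FALSE)
  }
  matrix(c((1 - p2 * alpha) / p1, alpha,
           alpha, (1 - p1 * alpha) / p2), 2, 2)
}

#' Next-generation analysis of a multigroup model
#'
#' Assembles the matrix of mean secondary infections per unit `R0`,
#' `m[l, l'] = p_l' * gamma[l, l'] * Sigma_l'`, and computes its spectral
#' radius by power iteration.  `R0 * rho > 1` is the multigroup endemic
#' threshold.
#'
#' @param groups A [group_model()].
#' @param r0 Optional basic reproduction number, for the verdict.
#' @return A list of class `next_gen` with `M`, `rho`, `Sigma` and, when
#'   `r0` is given, `r0_rho` and `endemic`.
#' @export
next_generation <- function(groups, r0 = NULL) {
  stopifnot(inherits(groups, "group_model"))
  if (!is_irreducible(groups$contact)) {
    stop(paste("the endemicity criterion requires an irreducible contact",
               "matrix; analyse isolated groups separately"), call. = FALSE)
  }
  L <- length(groups$p)
  M <- groups$contact *
    matrix(groups$p * groups$Sigma, L, L, byrow = TRUE)
  rho <- spectral_radius(M)
  out <- list(M = M, rho = rho, Sigma = groups$Sigma)
  if (!is.null(r0)) {
    out$r0_rho <- r0 * rho
    out$endemic <- out$r0_rho > 1
  }
  structure(out, class = "next_gen")
}

#' @export
print.next_gen <- function(x, ...) {
  cat(sprintf("<next_gen: rho = %.6g>\n", x$rho))
  if (!is.null(x$r0_rho)) {
    cat(sprintf("  R0 * rho = %.4g -> %s\n", x$r0_rho,
                if (x$endemic) "endemic equilibrium exists" else
                  "no endemic equilibrium"))
  }
  invisible(x)
}

# Spectral radius of a non-negative matrix by power iteration with
# Perron-vector normalization.  The iteration converges linearly at the
# eigenvalue ratio; the stopping rule bounds the true error through that
# ratio and the final estimate is Aitken-extrapolated, so slow spectra do
# not stall at the tolerance.
spectral_radius <- function(M, tol = 1e-14, max_iter = 100000L) {
  L <- nrow(M)
  v <- rep(1 / L, L)
  rho <- 0; d_prev <- NA_real_
  for (i in seq_len(max_iter)) {
    w <- as.vector(M %*% v)
    nw <- sum(w)
    if (nw == 0) return(0)
    rho_new <- nw / sum(v)
    v <- w / nw
    d <- rho_new - rho
    if (i > 2 && is.finite(d_prev) && abs(d_prev) > 0) {
      r <- d / d_prev
      if (is.finite(r) && abs(r) < 1) {
        err <- abs(d) * abs(r) / (1 - abs(r))
        if (err <= tol * max(rho_new, 1e-300) || abs(d) == 0) {
          return(rho_new + d * r / (1 - r))
        }
      }
    } else if (abs(d) <= 1e-16 * max(rho_new, 1e-300) && i > 1) {
      return(rho_new)
    }
    d_prev <- d
    rho <- rho_new
  }
  rho
}

#' Two-group spectral radius in closed form
#'
#' The leading eigenvalue of the equal-activity two-group next-generation
#' matrix, as an explicit root of its characteristic quadratic:
#' `rho(alpha)` is non-increasing and convex in the contact parameter, and
#' constant equal to `Sigma1` when the groups are vaccinated identically.
#'
#' @param p1 Weight of group 1.
#' @param sigma1,sigma2 Per-group stationary susceptibilities.
#' @param alpha Contact parameter (vectorized).
#' @return `rho(alpha)`.
#' @export
rho_of_alpha <- function(p1, sigma1, sigma2, alpha) {
  stopifnot(p1 > 0, p1 < 1)
  p2 <- 1 - p1
  tr <- (1 - p2 * alpha) * sigma1 + (1 - p1 * alpha) * sigma2
  det4 <- 4 * (1 - alpha) * sigma1 * sigma2
  0.5 * (tr + sqrt(pmax(tr^2 - det4, 0)))
}

#' Critical vaccination fraction
#'
#' In a well-mixed population where a fraction `p1` follows the recurrent
#' vaccination policy (stationary susceptibility `Sigma`) and the rest is
#' unvaccinated (susceptibility 1 under full waning), the spectral radius
#' is `1 - (1 - Sigma) p1` and the disease is kept from becoming endemic
#' if and only if `p1 >= p_c = (1 - 1/R0) / (1 - Sigma)`.  The factor
#' `1 - Sigma` plays the role of the efficacy of an imperfect vaccine in
#' the classical coverage threshold.
#'
#' @param r0 Basic reproduction number.
#' @param sigma Stationary susceptibility of the vaccinated group, `< 1`.
#' @return The critical adherence fraction (may be `<= 0` when `r0 <= 1`,
#'   or `> 1` when even full adherence cannot prevent endemicity).
#' @export
critical_vaccination_fraction <- function(r0, sigma) {
  stopifnot(r0 > 0)
  if (sigma >= 1) {
    stop("sigma must be < 1: the policy must block some transmission",
         call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be in [0, 1)", call. = FALSE)
  (1 - 1 / r0) / (1 - sigma)
}

#' Dose-budget-preserving allocations between two groups
#'
#' With `1/m` doses per unit time to split between two groups, the family
#' `T_1(beta) = T / (1 + beta p2)`, `T_2(beta) = T / (1 - beta p1)` spans
#' all allocations: `beta = 0` is the even split, `beta = 1/p1` gives all
#' doses to group 1 (group 2 unvaccinated), `beta = -1/p2` the reverse.
#' The dose budget `p1/E[T_1] + p2/E[T_2] = 1/m` holds identically in
#' `beta`.
#'
#' @param T_law A [duration_law()] with finite mean `m`.
#' @param beta Fairness parameter in `[-1/p2, 1/p1]`.
#' @param p1 Weight of group 1.
#' @return A list with `T1`, `T2` (duration laws; the infinite sentinel at
#'   the endpoints) and the means `m1`, `m2`.
#' @export
allocation_laws <- function(T_law, beta, p1) {
  stopifnot(inherits(T_law, "duration_law"), p1 > 0, p1 < 1,
            is.finite(law_mean(T_law)))
  p2 <- 1 - p1
  if (beta < -1 / p2 - 1e-12 || beta > 1 / p1 + 1e-12) {
    stop(sprintf("beta must lie in [%g, %g]", -1 / p2, 1 / p1),
         call. = FALSE)
  }
  c1 <- 1 + beta * p2
  c2 <- 1 - beta * p1
  T1 <- if (c1 <= 1e-12) duration_law("infinite") else law_scale(T_law, 1 / c1)
  T2 <- if (c2 <= 1e-12) duration_law("infinite") else law_scale(T_law, 1 / c2)
  list(T1 = T1, T2 = T2, m1 = law_mean(T1), m2 = law_mean(T2))
}

#' Fair-allocation analysis of a fixed dose budget
#'
#' For each fairness parameter `beta` and contact parameter `alpha`,
#' computes the per-group stationary susceptibilities under the
#' budget-preserving allocation [allocation_laws()] and the resulting
#' two-group spectral radius.  For assortative or well-mixed contacts
#' (`alpha <= 1`) the radius is minimal at the even split `beta = 0`:
#' unequal allocation always makes endemicity easier.  At the endpoints
#' one group is unvaccinated and its susceptibility is the long-age limit
#' of the mean curve (1 under full waning).
#'
#' @param T_law A [duration_law()] with finite mean: the booster interval
#'   under the even split.
#' @param p1 Weight of group 1.
#' @param sus A [susceptibility_law()].
#' @param beta Vector of fairness parameters.
#' @param alpha Vector of contact parameters.
#' @return A tibble with columns `alpha`, `beta`, `sigma1`, `sigma2`,
#'   `rho`, `inv_rho`, `m1`, `m2`.
#' @export
fair_allocation <- function(T_law, p1, sus, beta = NULL, alpha = 1) {
  stopifnot(inherits(sus, "susceptibility_law"))
  p2 <- 1 - p1
  if (is.null(beta)) beta <- seq(-1 / p2, 1 / p1, length.out = 41L)
  grid <- tidyr::expand_grid(alpha = alpha, beta = beta)
  rows <- purrr::pmap_dfr(grid, function(alpha, beta) {
    al <- allocation_laws(T_law, beta, p1)
    s1 <- if (al$T1$is_infinite) sigma_limit(sus) else
      stationary_susceptibility(sus, al$T1)
    s2 <- if (al$T2$is_infinite) sigma_limit(sus) else
      stationary_susceptibility(sus, al$T2)
    rho <- rho_of_alpha(p1, s1, s2, alpha)
    tibble::tibble(alpha = alpha, beta = beta, sigma1 = s1, sigma2 = s2,
                   rho = rho, inv_rho = 1 / rho, m1 = al$m1, m2 = al$m2)
  })
  rows
}

#' Solve the multigroup large-population limit
#'
#' The coupled Volterra system of the multigroup model: each group has its
#' own boundary fluxes and force of infection, and the force experienced
#' by group `l` is `sum_l' gamma[l', l] Lambda_l'`.  Masses are normalized
#' so that group `l` carries total mass `p_l`.
#'
#' @param groups A [group_model()].
#' @inheritParams solve_volterra
#' @return A `multigroup_solution` with a long tibble `$tab` (columns
#'   `group`, `t`, `prevalence`, `susceptible_mass`, `Lambda`, `x`, `y`)
#'   and a `$total` tibble.
#' @export
solve_multigroup_volterra <- function(groups, dt = 0.05, tmax = 100,
                                      density_times = numeric(0),
                                      n_step_nodes = 256L,
                                      init_cohorts = 1024L,
                                      picard_tol = 1e-10, picard_max = 200L,
                                      mass_tol = 0.05) {
  stopifnot(inherits(groups, "group_model"))
  spec0 <- model_spec(groups$infectiousness, groups$susceptibility,
                      groups$vaccination[[1]], i0 = groups$i0,
                      h_i = groups$h_i, h_s = groups$h_s)
  glist <- lapply(seq_along(groups$p), function(l) {
    g <- make_group(spec0, p = groups$p[l],
                    vaccination = groups$vaccination[[l]])
    # initial susceptible ages must be compatible with the group's own law
    if (is.null(groups$h_s) && !groups$vaccination[[l]]$is_infinite) {
      g$h_s <- residual_law(groups$vaccination[[l]])
    } else if (is.null(groups$h_s)) {
      g$h_s <- duration_law("exponential", rate = 1)
    }
    g
  })
  res <- volterra_impl(glist, contact = groups$contact, spec = spec0,
                       dt = dt, tmax = tmax, density_times = density_times,
                       n_step_nodes = n_step_nodes,
                       init_cohorts = init_cohorts,
                       picard_tol = picard_tol, picard_max = picard_max,
                       mass_tol = mass_tol)
  tab <- purrr::map_dfr(seq_along(res$group_tabs), function(l) {
    g <- res$group_tabs[[l]]
    tibble::tibble(group = l, t = res$times, prevalence = g$prevalence,
                   susceptible_mass = g$smass, Lambda = g$Lt,
                   x = g$x, y = g$y)
  })
  total <- tab |>
    dplyr::group_by(t) |>
    dplyr::summarise(prevalence = sum(prevalence),
                     susceptible_mass = sum(susceptible_mass),
                     .groups = "drop") |>
    dplyr::mutate(z = prevalence + susceptible_mass)
  res$tab <- tab
  res$total <- total
  res$groups <- groups
  class(res) <- "multigroup_solution"
  res
}

#' @export
print.multigroup_solution <- function(x, ...) {
  cat(sprintf("<multigroup_solution: %d groups, horizon %g>\n",
              length(x$group_tabs), x$tmax))
  cat(sprintf("  final total prevalence %.5g, mass drift %.2e\n",
              utils::tail(x$total$prevalence, 1), x$mass_drift))
  invisible(x)
}
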