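#' Compare the finite-population model with its deterministic limit
#'
#' Runs replicated individual-based simulations at one or more population
#' sizes alongside the Volterra solution of the limit, on a common output
#' grid.  As `N` grows the replicate-mean prevalence converges to the
#' deterministic prevalence (law of large numbers for the empirical age
#' measures).
#'
#' @param spec A [model_spec()].
#' @param n Vector of population sizes.
#' @param replicates Replicates per population size.
#' @param tmax Horizon.
#' @param dt_pde Grid step of the deterministic solver.
#' @param out_dt Trajectory sampling interval.
#' @param seed Seed.
#' @return A tibble with columns `method` (`"ibm"` or `"limit"`), `n`,
#'   `replicate` (`NA` for the limit), `t`, `prevalence`, `Lambda`.
#' @export
run_compare_limits <- function(spec, n = c(500, 2000, 8000),
                               replicates = 10L, tmax = 50,
                               dt_pde = 0.02, out_dt = 0.5, seed = 1L) {
  out_times <- seq(0, tmax, by = out_dt)
  sol <- solve_volterra(spec, dt = dt_pde, tmax = tmax)
  idx <- as.integer(round(out_times / dt_pde)) + 1L
  lim <- tibble::tibble(method = "limit", n = NA_integer_,
                        replicate = NA_integer_, t = out_times,
                        prevalence = sol$tab$prevalence[idx],
                        Lambda = sol$tab$Lambda[idx])
  ibm <- purrr::map_dfr(seq_along(n), function(k) {
    tr <- simulate_ibm(spec, n[k], tmax, replicates = replicates,
                       seed = seed + k, out_times = out_times)
    tibble::tibble(method = "ibm", n = n[k], replicate = tr$replicate,
                   t = tr$t, prevalence = tr$prevalence, Lambda = tr$Lambda)
  })
  dplyr::bind_rows(lim, ibm)
}

#' Bifurcation sweep of the deterministic limit
#'
#' Solves the limit to a long horizon over a grid of basic reproduction
#' numbers (and optionally of the susceptibility waning scale), recording
#' the terminal prevalence together with the analytic endemic threshold
#' `1/Sigma`.  Below the threshold the epidemic dies out, above it the
#' prevalence settles at the endemic level: the exchange of stability of
#' the two equilibria.
#'
#' @param spec A [model_spec()] (its transmission is rescaled at each `r0`).
#' @param r0_values Grid of basic reproduction numbers.
#' @param theta_sigma Optional grid of waning scales; when given,
#'   `spec_builder` must accept `(r0, theta)`.
#' @param spec_builder Function building the spec of one sweep point;
#'   defaults to rescaling `spec`.
#' @param tmax Horizon ("large time" at which prevalence is read).
#' @param dt Solver step.
#' @param extinct_below Terminal prevalence below this counts as extinct.
#' @return A tibble with `r0`, `theta_sigma`, `terminal_prevalence`,
#'   `threshold` (`1/Sigma`), `endemic`.
#' @export
run_bifurcation <- function(spec, r0_values, theta_sigma = NULL,
                            spec_builder = NULL, tmax = 300, dt = 0.025,
                            extinct_below = 1e-6) {
  if (is.null(spec_builder)) {
    spec_builder <- function(r0, theta) {
      if (!is.null(theta)) {
        model_spec(spec$infectiousness, sigma_gamma_cdf(4, theta),
                   spec$vaccination, i0 = spec$i0, h_i = spec$h_i,
                   h_s = spec$h_s, r0 = r0)
      } else {
        set_r0(spec, r0)
      }
    }
  }
  grid <- tidyr::expand_grid(
    r0 = r0_values,
    theta_sigma = if (is.null(theta_sigma)) NA_real_ else theta_sigma)
  purrr::pmap_dfr(grid, function(r0, theta_sigma) {
    sp <- spec_builder(r0, if (is.na(theta_sigma)) NULL else theta_sigma)
    sol <- solve_volterra(sp, dt = dt, tmax = tmax)
    tp <- utils::tail(sol$tab$prevalence, 1)
    tibble::tibble(r0 = r0, theta_sigma = theta_sigma,
                   terminal_prevalence = tp,
                   threshold = endemic_threshold(sp),
                   endemic = tp >= extinct_below)
  })
}

#' Allocation scan over the fairness parameter
#'
#' The Fig.-style experiment behind the fair-allocation result: for each
#' contact parameter `alpha`, scan the fairness parameter `beta` of the
#' dose-budget-preserving allocation and record `1/rho`.  For
#' `alpha <= 1` the threshold `1/rho` is maximal at the even split.
#'
#' @param T_law Booster-interval law under the even split.
#' @param sus A [susceptibility_law()].
#' @param p1 Weight of group 1.
#' @param alpha Vector of contact parameters.
#' @param n_beta Number of beta grid points.
#' @return The [fair_allocation()] tibble.
#' @export
run_allocation_scan <- function(T_law, sus, p1 = 0.5,
                                alpha = c(0, 0.25, 0.5, 1), n_beta = 41L) {
  p2 <- 1 - p1
  beta <- seq(-1 / p2, 1 / p1, length.out = n_beta)
  fair_allocation(T_law, p1, sus, beta = beta, alpha = alpha)
}
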