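#' Solve the large-population limit of the epidemic
#'
#' Integrates the deterministic limit of the individual-based model: a
#' system of Volterra integral equations for the new-infection flux
#' `x(t) = I(t, 0)`, the new-susceptible flux `y(t) = S(t, 0)` and the force
#' of infection `Lambda(t)`, from which the age-structured densities
#' `I(t, a)` and `S(t, a)` of the underlying transport equations are
#' reconstructed along characteristics.  The conditioning of the
#' susceptibility curve on not having been infected (which survives in the
#' large-population limit for random curves) is handled exactly per birth
#' cohort.
#'
#' The scheme is a uniform time grid with product-trapezoidal convolutions
#' and per-step Picard iteration.  Initial age distributions are
#' discretized into equal-mass quantile cohorts, so population mass is
#' represented exactly.  Random step susceptibilities are integrated over
#' quantile nodes of the immune-window law `T_R`.
#'
#' @param spec A [model_spec()].
#' @param dt Time step (also the age resolution).
#' @param tmax Horizon.
#' @param density_times Times at which to record the full age densities
#'   (see [reconstruct_age_densities()]).
#' @param n_step_nodes Quantile nodes used for a random `T_R` in a step
#'   susceptibility law.
#' @param init_cohorts Number of equal-mass cohorts used to discretize each
#'   initial age density.
#' @param picard_tol,picard_max Per-step fixed-point tolerance and cap.
#' @param mass_tol Error if the conserved total mass drifts from 1 by more
#'   than this.
#' @return A `limit_solution`: prevalence, susceptible mass, force of
#'   infection and boundary fluxes on the time grid (a tibble in `$tab`),
#'   plus recorded densities.
#' @examples
#' spec <- default_model_spec(r0 = 3)
#' sol <- solve_volterra(spec, dt = 0.5, tmax = 50)
#' tail(sol$tab)
#' @export
solve_volterra <- function(spec, dt = 0.05, tmax = 100,
                           density_times = numeric(0),
                           n_step_nodes = 256L, init_cohorts = 1024L,
                           picard_tol = 1e-10, picard_max = 200L,
                           mass_tol = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  res <- volterra_impl(list(make_group(spec, p = 1)), contact = matrix(1, 1, 1),
                       spec = spec, dt = dt, tmax = tmax,
                       density_times = density_times,
                       n_step_nodes = n_step_nodes,
                       init_cohorts = init_cohorts,
                       picard_tol = picard_tol, picard_max = picard_max,
                       mass_tol = mass_tol)
  g <- res$group_tabs[[1]]
  res$tab <- tibble::tibble(
    t = res$times, prevalence = g$prevalence,
    susceptible_mass = g$smass, Lambda = g$Lt, x = g$x, y = g$y,
    sigma_bar = g$sigma_bar, z = g$prevalence + g$smass)
  res$spec <- spec
  class(res) <- "limit_solution"
  res
}

# Internal group descriptor for the solver: per-group weight, vaccination
# law and (optionally) its own initial condition scale.
make_group <- function(spec, p, vaccination = NULL) {
  list(p = p,
       vaccination = vaccination %||% spec$vaccination,
       i0 = spec$i0, h_i = spec$h_i, h_s = spec$h_s)
}

# Shared driver behind solve_volterra() and solve_multigroup_volterra().
volterra_impl <- function(glist, contact, spec, dt, tmax, density_times,
                          n_step_nodes, init_cohorts, picard_tol,
                          picard_max, mass_tol) {
  stopifnot(dt > 0, tmax > dt)
  inf <- spec$infectiousness
  sus <- spec$susceptibility
  if (inf$lambda_max * dt >= 0.1) {
    stop("dt too coarse for this transmission rate: need lambda_max * dt < 0.1",
         call. = FALSE)
  }
  nt <- as.integer(round(tmax / dt))
  ti_law <- inf$duration

  # initial-age cohorts: equal-mass quantile midpoints rounded to the grid
  cohort_ages <- function(law, nb) {
    if (law$is_point_mass) {
      list(ib = as.integer(round((law$pars$value + law$shift) / dt)), w = 1)
    } else {
      q <- law_quantile(law, (seq_len(nb) - 0.5) / nb)
      list(ib = as.integer(round(q / dt)), w = rep(1 / nb, nb))
    }
  }

  cohs <- lapply(glist, function(g) {
    list(I = cohort_ages(g$h_i, init_cohorts),
         S = cohort_ages(g$h_s, init_cohorts))
  })
  maxib <- max(vapply(cohs, function(ch) max(ch$I$ib, ch$S$ib), numeric(1)))
  nj <- nt + as.integer(maxib)
  ages <- (0:nj) * dt

  ml <- mean_infectiousness(inf, ages)
  upI <- law_upper(ti_law)
  # survival grid rebuilt as the trapezoid partial integral of the density
  # grid, so the discrete removal flux and the discrete mass loss agree
  # exactly (for smooth laws this is an O(dt^2) change)
  consistent_survival <- function(f) {
    s <- 1 - c(0, cumsum(dt * (f[-1] + f[-length(f)]) / 2))
    pmin(pmax(s, 0), 1)
  }
  kernel_grids <- function(law) {
    if (law$is_infinite) {
      list(f = numeric(nj + 1), s = rep(1, nj + 1))
    } else if (law$is_point_mass || law$family == "twopoint") {
      # atoms become split grid deltas and cell-averaged survivals, so the
      # discrete removal flux matches the discrete mass loss to O(dt^2)
      atoms <- if (law$is_point_mass) {
        list(v = law$pars$value + law$shift, w = 1)
      } else {
        list(v = c(law$pars$value1, law$pars$value2) + law$shift,
             w = c(law$pars$prob, 1 - law$pars$prob))
      }
      f <- numeric(nj + 1)
      for (k in seq_along(atoms$v)) {
        u <- atoms$v[k] / dt
        if (u < 1) stop("atom durations must exceed dt", call. = FALSE)
        j0 <- floor(u); frac <- u - j0
        if (j0 <= nj) f[j0 + 1] <- f[j0 + 1] + atoms$w[k] * (1 - frac) / dt
        if (j0 + 1 <= nj) f[j0 + 2] <- f[j0 + 2] + atoms$w[k] * frac / dt
      }
      list(f = f, s = consistent_survival(f))
    } else {
      # cell-averaged density: the exact probability mass of each grid
      # cell, so the discrete kernel mass telescopes to one for every law
      # (uniform edges and steep densities included); equals the midpoint
      # density up to O(dt^2) when the density is smooth
      f <- numeric(nj + 1)
      f[1] <- (1 - law_survival(law, dt / 2)) / (dt / 2)
      mid <- (1:nj) * dt
      f[-1] <- (law_survival(law, mid - dt / 2) -
                  law_survival(law, mid + dt / 2)) / dt
      list(f = f, s = consistent_survival(f))
    }
  }
  kTI <- kernel_grids(ti_law)
  naI <- if (is.finite(upI)) min(nt, as.integer(ceiling(upI / dt)) + 2L) else nt
  naL <- naI

  # susceptibility representation
  if (sus$kind == "step") {
    sigma_type <- 1L
    rec <- sus$recovery
    thr <- if (rec$is_point_mass) {
      rec$pars$value + rec$shift
    } else if (rec$is_infinite) {
      Inf
    } else {
      law_quantile(rec, (seq_len(n_step_nodes) - 0.5) / n_step_nodes)
    }
    sigma_curves <- matrix(0, 1, 1)
    sigma_thr <- sort(thr)
  } else {
    sigma_type <- 0L
    curves <- if (sus$kind == "deterministic") list(sus$fn) else sus$curves
    K <- length(curves)
    if (K * (nj + 1) > 6e7) {
      stop("susceptibility panel too large for this grid; reduce the panel",
           call. = FALSE)
    }
    sigma_curves <- do.call(rbind, lapply(curves, function(f) f(ages)))
    sigma_thr <- numeric(0)
  }

  groups_cpp <- vector("list", length(glist))
  for (gi in seq_along(glist)) {
    g <- glist[[gi]]
    kTV <- kernel_grids(g$vaccination)
    ch <- cohs[[gi]]
    sI <- kTI$s[ch$I$ib + 1]
    if (any(sI < 1e-15)) {
      bad <- ch$I$ib[which(sI < 1e-15)[1]] * dt
      stop(sprintf(
        "initial infected age %g is beyond the infectious-period support",
        bad), call. = FALSE)
    }
    sS <- kTV$s[ch$S$ib + 1]
    if (any(sS < 1e-15)) {
      bad <- ch$S$ib[which(sS < 1e-15)[1]] * dt
      stop(sprintf(
        "initial susceptible age %g is beyond the vaccination support",
        bad), call. = FALSE)
    }
    groups_cpp[[gi]] <- list(
      p = g$p, fTV = kTV$f, STV = kTV$s,
      ibI = ch$I$ib, wI = g$p * g$i0 * ch$I$w / sI,
      ibS = ch$S$ib, wS = g$p * (1 - g$i0) * ch$S$w / sS)
  }

  dsteps <- sort(unique(as.integer(round(density_times / dt))))
  dsteps <- dsteps[dsteps >= 0 & dsteps <= nt]

  raw <- cpp_solve_volterra(dt, nt, nj, ml, kTI$f, kTI$s,
                            naI, naL, groups_cpp, contact,
                            sigma_type, sigma_curves, sigma_thr,
                            picard_tol, as.integer(picard_max),
                            dsteps)

  times <- (0:nt) * dt
  group_tabs <- lapply(raw$groups, function(gg) {
    tibble::tibble(x = gg$x, y = gg$y, L = gg$L, Lt = gg$Lt,
                   prevalence = gg$prevalence, smass = gg$smass,
                   sigma_bar = gg$sigma_bar)
  })

  # diagnostics: conservation and the a-priori bound x <= Lambda
  ptot <- Reduce(`+`, lapply(group_tabs, function(g) g$prevalence + g$smass))
  drift <- max(abs(ptot - 1))
  if (drift > mass_tol) {
    stop(sprintf(
      "mass conservation drifted by %.3g (tolerance %g); use a smaller dt",
      drift, mass_tol), call. = FALSE)
  }
  for (g in group_tabs) {
    if (any(g$x > g$Lt * (1 + 1e-6) + 1e-10)) {
      stop("internal consistency failure: x(t) exceeded the force of infection",
           call. = FALSE)
    }
  }

  list(times = times, dt = dt, tmax = tmax, nt = nt,
       group_tabs = group_tabs, mass_drift = drift,
       density_ages = ages, density_steps = dsteps,
       densities = raw$densities)
}

#' @export
print.limit_solution <- function(x, ...) {
  cat(sprintf("<limit_solution: dt = %g, horizon %g>\n", x$dt, x$tmax))
  cat(sprintf("  final prevalence %.5g, mass drift %.2e\n",
              utils::tail(x$tab$prevalence, 1), x$mass_drift))
  invisible(x)
}

#' Reconstruct the age-structured densities of a limit solution
#'
#' Returns `I(t, a)` and `S(t, a)` along the characteristics: cohorts born
#' after time 0 carry the survival of their infectious period or of the
#' vaccination renewal times the exposure-conditioning factor, cohorts
#' present at time 0 carry the corresponding conditional survivals.
#' Densities are recorded during [solve_volterra()] at `density_times`.
#'
#' @param sol A `limit_solution` solved with non-empty `density_times`.
#' @param amax Optional truncation for the returned age range.
#' @return A tibble with columns `t`, `a`, `I`, `S` (and `group` for
#'   multigroup solutions).
#' @export
reconstruct_age_densities <- function(sol, amax = NULL) {
  stopifnot(inherits(sol, c("limit_solution", "multigroup_solution")))
  if (length(sol$density_steps) == 0) {
    stop("solve with density_times to record age densities", call. = FALSE)
  }
  ages <- sol$density_ages
  keep <- if (is.null(amax)) seq_along(ages) else which(ages <= amax)
  out <- purrr::map_dfr(seq_along(sol$density_steps), function(i) {
    tt <- sol$density_steps[i] * sol$dt
    purrr::map_dfr(seq_along(sol$densities[[i]]), function(g) {
      d <- sol$densities[[i]][[g]]
      tibble::tibble(group = g, t = tt, a = ages[keep],
                     I = d$I[keep], S = d$S[keep])
    })
  })
  if (length(sol$group_tabs) == 1L) out$group <- NULL
  out
}

#' Force of infection of a limit solution
#'
#' The cached `Lambda(t)` on the solution grid, defined equivalently as the
#' integral of the conditional mean infectiousness against `I(t, a)` or as
#' the convolution of the unconditional mean curve with the past infection
#' flux.
#'
#' @param sol A `limit_solution`.
#' @param t Times (rounded to the grid).
#' @return Numeric vector of rates.
#' @export
force_of_infection <- function(sol, t) {
  stopifnot(inherits(sol, "limit_solution"))
  idx <- as.integer(round(t / sol$dt))
  if (any(idx < 0 | idx > sol$nt)) {
    stop("t outside the solved horizon", call. = FALSE)
  }
  sol$tab$Lambda[idx + 1]
}

#' Exposure-conditioned mean susceptibility
#'
#' The expected susceptibility of an individual of class age `a` that has
#' been exposed to a force-of-infection history `L` since its last
#' immunizing event without getting infected:
#' `E[sigma(a) e^{-int_0^a L(u) sigma(u) du}] / E[e^{-int_0^a L sigma}]`.
#' Surviving exposure biases the susceptibility downward; the bias vanishes
#' for a deterministic curve and when `L = 0`.
#'
#' @param sus A [susceptibility_law()].
#' @param L Either a single rate (constant exposure) or a vectorized
#'   function of time-in-class `u` in `[0, a]`.
#' @param a Class age.
#' @param n_nodes Unused for step laws with a density (the exact law is
#'   integrated); kept for compatibility.
#' @return A number in `[0, 1]`.
#' @export
exposure_weighted_susceptibility <- function(sus, L, a, n_nodes = 512L) {
  stopifnot(inherits(sus, "susceptibility_law"), a >= 0)
  Lf <- if (is.function(L)) L else function(u) rep(L, length(u))
  if (sus$kind == "deterministic") {
    return(sus$fn(a))
  }
  if (sus$kind == "step") {
    rec <- sus$recovery
    if (rec$is_infinite) return(0)
    if (a == 0) return(mean_susceptibility(sus, 0))
    CL <- cum_integral(Lf, a, n = 8192L)
    CLa <- CL(a)
    eQ <- function(r) exp(-(CLa - CL(pmin(pmax(r, 0), a)))) # e^{-int_r^a L}
    if (rec$is_point_mass || rec$family == "twopoint") {
      v <- if (rec$is_point_mass) rec$pars$value + rec$shift else
        c(rec$pars$value1, rec$pars$value2) + rec$shift
      w <- if (rec$is_point_mass) 1 else
        c(rec$pars$prob, 1 - rec$pars$prob)
      num <- sum(w * ifelse(v <= a, eQ(v), 0))
      den <- sum(w * ifelse(v <= a, eQ(v), 1))
    } else {
      num <- stats::integrate(function(r) law_density(rec, r) * eQ(r),
                              0, a, rel.tol = 1e-12,
                              subdivisions = 2000L,
                              stop.on.error = FALSE)$value
      den <- law_survival(rec, a) + num
    }
    return(num / den)
  }
  # panel: direct quadrature per curve
  grid <- seq(0, a, length.out = 513L)
  lg <- Lf(grid)
  vals <- vapply(sus$curves, function(f) {
    sg <- f(grid)
    q <- sum((lg * sg)[-1] + (lg * sg)[-length(grid)]) / 2 *
      (grid[2] - grid[1])
    c(f(a) * exp(-q), exp(-q))
  }, numeric(2))
  sum(vals[1, ]) / sum(vals[2, ])
}
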