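#' Initialize a finite population
#'
#' Draws the initial state of the individual-based model: each individual
#' independently is infected with probability `i0`, gets a class age from
#' `h_i` (infected) or `h_s` (susceptible), and then — for infected
#' individuals — an infectious period conditioned to exceed the age (so the
#' individual is still infectious), or — for susceptibles — an unconditioned
#' susceptibility curve and a residual booster time conditioned to exceed
#' the age.
#'
#' @param spec A [model_spec()].
#' @param n Population size.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return An object of class `population_state`.
#' @export
ibm_init <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  inf <- spec$infectiousness
  sus <- spec$susceptibility
  state <- stats::rbinom(n, 1, spec$i0)
  age <- numeric(n)
  iI <- which(state == 1L)
  iS <- which(state == 0L)
  age[iI] <- law_sample(spec$h_i, length(iI))
  age[iS] <- law_sample(spec$h_s, length(iS))
  tau <- -age
  sched <- rep(Inf, n)
  lam_val <- numeric(n)
  wane_t <- rep(Inf, n)
  sig_idx <- integer(n)

  if (length(iI) > 0) {
    ti <- law_sample_conditional(inf$duration, age[iI])
    sched[iI] <- tau[iI] + ti
    if (inf$kind == "constant") lam_val[iI] <- inf$rate
  }
  if (length(iS) > 0) {
    if (!spec$vaccination$is_infinite) {
      tv <- law_sample_conditional(spec$vaccination, age[iS])
      sched[iS] <- tau[iS] + tv
    }
    if (sus$kind == "step") {
      wane_t[iS] <- tau[iS] + law_sample(sus$recovery, length(iS))
    } else if (sus$kind == "panel") {
      sig_idx[iS] <- sample.int(length(sus$curves), length(iS),
                                replace = TRUE) - 1L
    }
  }
  structure(list(spec = spec, n = n, t = 0, state = state, tau = tau,
                 sched = sched, lam_val = lam_val, wane_t = wane_t,
                 sig_idx = sig_idx, incidence = 0),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state: N = %d, t = %g, #I = %d>\n",
              x$n, x$t, sum(x$state == 1L)))
  invisible(x)
}

encode_law <- function(law) {
  stopifnot(inherits(law, "duration_law"))
  switch(law$family,
    exponential = c(1, law$pars$rate, 0, law$shift),
    gamma = c(2, law$pars$shape, law$pars$scale, law$shift),
    uniform = c(3, law$pars$min, law$pars$max, law$shift),
    point = c(4, law$pars$value, 0, law$shift),
    infinite = c(5, 0, 0, 0),
    stop(sprintf(
      "duration family '%s' cannot be resampled inside the simulator",
      law$family), call. = FALSE))
}

#' Simulate the individual-based epidemic
#'
#' Advances a [ibm_init()] population to `tmax` by exact event-driven
#' simulation and records the trajectory on a sampling grid.  The
#' population state is returned updated, so simulation can be continued.
#'
#' @param pop A `population_state`.
#' @param tmax End time.
#' @param out_dt Sampling interval of the trajectory.
#' @param out_times Explicit sampling times (overrides `out_dt`).
#' @param event_log If `TRUE`, also return the full event log.
#' @return A list with `trajectory` (tibble `t`, `prevalence`, `Lambda`,
#'   `incidence`), the updated `pop`, and optionally `log` (tibble `t`,
#'   `individual`, `event` in infect/recover/vaccinate).
#' @export
ibm_simulate <- function(pop, tmax, out_dt = 0.5, out_times = NULL,
                         event_log = FALSE) {
  stopifnot(inherits(pop, "population_state"), tmax > pop$t)
  spec <- pop$spec
  inf <- spec$infectiousness
  sus <- spec$susceptibility
  if (!is.finite(inf$lambda_max)) {
    stop("the thinning bound requires a finite lambda_max", call. = FALSE)
  }
  if (is.null(out_times)) {
    out_times <- seq(pop$t, tmax, by = out_dt)
  }
  stopifnot(all(diff(out_times) > 0), all(out_times >= pop$t),
            all(out_times <= tmax))

  # transmission curve representation
  if (inf$kind == "constant") {
    lam_type <- 0L; lam_grid <- 0; lam_dx <- 1
  } else {
    lam_type <- 1L
    up <- law_upper(inf$duration)
    if (!is.finite(up)) up <- 100 * law_mean(inf$duration)
    lam_dx <- up / 4095
    lam_grid <- inf$shape_fun(seq(0, up, by = lam_dx))
  }

  # susceptibility representation
  if (sus$kind == "step") {
    sig_type <- 1L
    sig_curves <- matrix(0, 1, 1); sig_dx <- 1; npanel <- 1L
    law_tr <- encode_law(sus$recovery)
  } else {
    sig_type <- 0L
    a_top <- tmax - min(pop$tau) + 1
    sig_dx <- a_top / 8191
    agrid <- seq(0, a_top, by = sig_dx)
    curves <- if (sus$kind == "deterministic") list(sus$fn) else sus$curves
    npanel <- length(curves)
    sig_curves <- do.call(rbind, lapply(curves, function(f) f(agrid)))
    law_tr <- c(5, 0, 0, 0)
  }

  res <- cpp_simulate_ibm(
    state = as.integer(pop$state), tau = as.numeric(pop$tau),
    sched = as.numeric(pop$sched), lam_val = as.numeric(pop$lam_val),
    wane_t = as.numeric(pop$wane_t), sig_idx = as.integer(pop$sig_idx),
    lam_type = lam_type, lam_rate = inf$rate %||% 0,
    lam_grid = as.numeric(lam_grid), lam_dx = lam_dx,
    lam_max = inf$lambda_max,
    sig_type = sig_type, sig_curves = sig_curves, sig_dx = sig_dx,
    law_TI = encode_law(inf$duration), law_TV = encode_law(spec$vaccination),
    law_TR = law_tr, sig_npanel = npanel,
    t0 = pop$t, tmax = tmax, out_times = as.numeric(out_times),
    keep_log = event_log, incidence0 = pop$incidence)

  pop$state <- res$state; pop$tau <- res$tau; pop$sched <- res$sched
  pop$wane_t <- res$wane_t; pop$sig_idx <- res$sig_idx
  pop$lam_val <- res$lam_val
  pop$t <- res$t_end; pop$incidence <- res$final_incidence

  out <- list(
    trajectory = tibble::tibble(t = res$times, prevalence = res$prevalence,
                                Lambda = res$Lambda,
                                incidence = res$incidence),
    pop = pop)
  if (event_log) {
    out$log <- tibble::tibble(
      t = res$log_t, individual = res$log_id,
      event = c("infect", "recover", "vaccinate")[res$log_kind + 1L])
  }
  out
}

#' Replicated individual-based simulations
#'
#' Convenience wrapper: initializes and simulates `replicates` independent
#' populations, each from a sub-seed derived from `seed`, and returns a
#' tidy trajectory table.
#'
#' @inheritParams ibm_init
#' @inheritParams ibm_simulate
#' @param replicates Number of independent runs.
#' @return A tibble with columns `replicate`, `t`, `prevalence`, `Lambda`,
#'   `incidence`, of class `ibm_trajectory`.
#' @export
simulate_ibm <- function(spec, n, tmax, replicates = 1L, seed = 1L,
                         out_dt = 0.5, out_times = NULL) {
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, replicates)
  tab <- purrr::map_dfr(seq_len(replicates), function(r) {
    pop <- ibm_init(spec, n, seed = subseeds[r])
    tr <- ibm_simulate(pop, tmax, out_dt = out_dt,
                       out_times = out_times)$trajectory
    tr$replicate <- r
    tr
  })
  out <- tab[, c("replicate", "t", "prevalence", "Lambda", "incidence")]
  class(out) <- c("ibm_trajectory", class(out))
  out
}

#' Empirical class-age histograms of a population
#'
#' The finite-population analogue of the age densities `I(t, a)` and
#' `S(t, a)`: per-compartment histograms of the times since each
#' individual's last event, with atom mass `1/N`, so that the total mass
#' equals the compartment fractions and converges to the deterministic
#' densities in large populations.
#'
#' @param pop A `population_state`.
#' @param bin_width Positive histogram bin width.
#' @return A tibble with columns `compartment`, `a_lo`, `a_hi`, `mass`,
#'   `density`.
#' @export
empirical_age_measures <- function(pop, bin_width) {
  stopifnot(inherits(pop, "population_state"), bin_width > 0)
  ages <- pop$t - pop$tau
  lab <- ifelse(pop$state == 1L, "I", "S")
  brk <- seq(0, max(ages) + bin_width, by = bin_width)
  purrr::map_dfr(c("I", "S"), function(cc) {
    h <- graphics::hist(ages[lab == cc], breaks = brk, plot = FALSE)
    tibble::tibble(compartment = cc, a_lo = utils::head(brk, -1),
                   a_hi = brk[-1], mass = h$counts / pop$n,
                   density = h$counts / pop$n / bin_width)
  })
}
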