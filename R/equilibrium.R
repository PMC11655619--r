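#' Disease-free equilibrium age profile
#'
#' With no infections, susceptible individuals are only vaccinated, at
#' renewal times distributed as `T_V`; the stationary age-since-last-dose
#' profile is `S(a) = P(T_V > a) / E[T_V]`, a probability density.
#'
#' @param vac A [duration_law()] with finite mean.
#' @param ages Age grid on which to evaluate the profile.
#' @return A tibble with columns `a` and `S`.
#' @export
disease_free_equilibrium <- function(vac, ages) {
  stopifnot(inherits(vac, "duration_law"))
  if (vac$is_infinite) {
    stop("the disease-free profile needs a finite mean vaccination law",
         call. = FALSE)
  }
  tibble::tibble(a = ages, S = law_survival(vac, ages) / law_mean(vac))
}

# Fast deterministic/mean cumulative susceptibility with linear tail
# extension, used inside the endemic-function quadratures.
make_phi <- function(sus, a_hint = 0) {
  slim <- sigma_limit(sus)
  # find where the mean curve has plateaued
  A <- max(a_hint, 1)
  while (A < 1e4 && mean_susceptibility(sus, A) < slim - 1e-9) A <- A * 2
  grid <- seq(0, A, length.out = 8192L)
  ms <- mean_susceptibility(sus, grid)
  ph <- c(0, cumsum(diff(grid) * (ms[-1] + ms[-length(ms)]) / 2))
  pf <- stats::approxfun(grid, ph)
  phiA <- ph[length(ph)]
  sA <- ms[length(ms)]
  list(phi = function(a) ifelse(a <= A, pf(pmin(a, A)), phiA + (a - A) * sA),
       A = A, slope_end = sA)
}

# Smooth cumulative integral of f on [0, up]: composite Simpson on a fine
# grid, interpolated with a natural spline (both fourth order).
cum_integral <- function(f, up, n = 16384L) {
  n <- as.integer(n); if (n %% 2L == 1L) n <- n + 1L
  h <- up / n
  x <- seq(0, up, length.out = n + 1L)
  y <- f(x)
  cs <- numeric(n + 1L)
  ev <- seq(1L, n - 1L, by = 2L)
  pair <- h / 3 * (y[ev] + 4 * y[ev + 1L] + y[ev + 2L])
  cs[ev + 2L] <- cumsum(pair)
  cs[ev + 1L] <- cs[ev] + h / 12 * (5 * y[ev] + 8 * y[ev + 1L] - y[ev + 2L])
  sf <- stats::splinefun(x, cs, method = "natural")
  function(t) ifelse(t <= 0, 0,
                     ifelse(t >= up, cs[n + 1L], sf(pmin(pmax(t, 0), up))))
}

# Quantile nodes of the immune-window law of a step susceptibility.
tr_nodes <- function(rec, n_nodes = 512L) {
  if (rec$is_point_mass) rec$pars$value + rec$shift
  else if (rec$is_infinite) Inf
  else law_quantile(rec, (seq_len(n_nodes) - 0.5) / n_nodes)
}

#' Endemic function
#'
#' The scalar function whose roots characterize endemic equilibria: an
#' endemic equilibrium with infection pressure `x = R0 * I(0)` exists for
#' every positive solution of `F_e(x) = R0`, with
#' `F_e(x) = x E[T_I] + x E[int_0^{T_V} e^{-x phi(a)} da] /
#' E[1 - e^{-x phi(T_V)}]` and `phi(a) = int_0^a sigma(u) du` per
#' realization.  `F_e` decreases to `1/Sigma` as `x -> 0` and is increasing
#' for deterministic and step susceptibility curves, which yields the
#' endemic threshold `R0 * Sigma > 1`.
#'
#' For a step law a closed form is available
#' (`x E[T_I] + 1 + x E[T_V ^ T_R] / E[1 - e^{-x (T_V - T_R)_+}]`); the
#' generic quadrature route is kept as an independent cross-check.
#'
#' @param x Positive infection pressure at equilibrium (vectorized).
#' @param spec A [model_spec()].
#' @param method `"auto"` (closed form for step laws), `"quadrature"`, or
#'   `"closed_form"` (step laws only).
#' @param n_nodes Quantile nodes for random `T_R`.
#' @return `F_e(x)`, same length as `x`.
#' @seealso [endemic_function_limit()] for the `x -> 0` limit `1/Sigma`,
#'   computed without cancellation.
#' @export
endemic_function <- function(x, spec, method = c("auto", "quadrature",
                                                 "closed_form"),
                             n_nodes = 512L) {
  stopifnot(inherits(spec, "model_spec"))
  method <- match.arg(method)
  if (any(x <= 0)) {
    stop("x must be positive; use endemic_function_limit() for x -> 0",
         call. = FALSE)
  }
  sus <- spec$susceptibility
  vac <- spec$vaccination
  eti <- law_mean(spec$infectiousness$duration)
  if (method == "auto") {
    method <- if (sus$kind == "step") "closed_form" else "quadrature"
  }
  if (method == "closed_form" && sus$kind != "step") {
    stop("the closed form applies to step susceptibility laws only",
         call. = FALSE)
  }
  vapply(x, function(xx) {
    x_eti <- xx * eti
    if (sus$kind == "step") {
      r <- tr_nodes(sus$recovery, n_nodes)
      # D = E[1 - e^{-x (T_V - T_R)_+}] = int x e^{-x w} P(T_V - T_R > w) dw
      pW <- function(w) {
        vapply(w, function(ww) mean(law_survival(vac, r + ww)), numeric(1))
      }
      upD <- if (vac$is_infinite) Inf else law_upper(vac)
      D <- if (vac$is_infinite) {
        # T_V infinite: (T_V - T_R)_+ infinite whenever T_R finite
        mean(is.finite(r))
      } else {
        stats::integrate(function(w) xx * exp(-xx * w) * pW(w), 0,
                         min(upD, 746 / xx), rel.tol = 1e-12,
                         subdivisions = 2000L, stop.on.error = FALSE)$value
      }
      if (D <= 0) return(Inf)
      if (method == "closed_form") {
        # E[T_V ^ T_R] = E_r[int_0^r S_V], with T_R on the same quantile
        # nodes as the other expectations
        upV <- law_upper(vac)
        csv <- cum_integral(function(a) law_survival(vac, a), upV)
        ET <- mean(csv(pmin(r, upV)))
        x_eti + 1 + xx * ET / D
      } else {
        # N = int S_V(a) E_r[e^{-x (a - r)_+}] da on a fine Simpson grid;
        # the inner expectation is accumulated node by node so the kinked
        # integrand is evaluated exactly at every grid point
        if (vac$is_infinite) return(Inf)
        upV <- law_upper(vac)
        ng <- 65536L
        grid <- seq(0, upV, length.out = ng + 1L)
        g <- numeric(ng + 1L)
        rs <- sort(r)
        for (k in seq_along(rs)) {
          idx <- findInterval(rs[k], grid)
          if (idx >= 1L) g[seq_len(idx)] <- g[seq_len(idx)] + 1
          if (idx < ng + 1L) {
            tail_idx <- (idx + 1L):(ng + 1L)
            g[tail_idx] <- g[tail_idx] + exp(-xx * (grid[tail_idx] - rs[k]))
          }
        }
        iv <- law_survival(vac, grid) * g / length(rs)
        h <- upV / ng
        ev <- seq(1L, ng - 1L, by = 2L)
        N <- sum(h / 3 * (iv[ev] + 4 * iv[ev + 1L] + iv[ev + 2L]))
        x_eti + xx * N / D
      }
    } else if (sus$kind == "deterministic") {
      ph <- make_phi(sus, a_hint = if (vac$is_infinite) 0 else law_upper(vac))
      phi <- ph$phi
      up <- if (vac$is_infinite) Inf else law_upper(vac)
      # truncate where the integrand has decayed
      upN <- if (is.finite(up)) up else {
        A <- ph$A
        while (xx * phi(A) < 46 && A < 1e8) A <- A * 2
        A
      }
      N <- stats::integrate(function(a) {
        law_survival(vac, a) * exp(-xx * phi(a))
      }, 0, upN, rel.tol = 1e-12, subdivisions = 2000L,
      stop.on.error = FALSE)$value
      D <- if (vac$is_infinite) {
        if (ph$slope_end > 0) 1 else 1 - exp(-xx * phi(1e8))
      } else if (vac$is_point_mass) {
        1 - exp(-xx * phi(law_mean(vac)))
      } else {
        stats::integrate(function(a) {
          law_density(vac, a) * (1 - exp(-xx * phi(a)))
        }, 0, up, rel.tol = 1e-12, subdivisions = 2000L,
        stop.on.error = FALSE)$value
      }
      if (D <= 0) return(Inf)
      x_eti + xx * N / D
    } else { # panel: average the realization-wise functionals
      if (vac$is_infinite) {
        stop("panel susceptibility with no vaccination is not supported here",
             call. = FALSE)
      }
      up <- law_upper(vac)
      grid <- seq(0, up, length.out = 4096L)
      dg <- grid[2] - grid[1]
      sv <- law_survival(vac, grid)
      Ns <- Ds <- numeric(length(sus$curves))
      fv <- if (vac$is_point_mass) NULL else law_density(vac, grid)
      for (k in seq_along(sus$curves)) {
        sg <- sus$curves[[k]](grid)
        phk <- c(0, cumsum(dg * (sg[-1] + sg[-length(sg)]) / 2))
        e <- exp(-xx * phk)
        Ns[k] <- sum(dg * ((sv * e)[-1] + (sv * e)[-length(e)]) / 2)
        Ds[k] <- if (vac$is_point_mass) 1 - e[length(e)] else
          sum(dg * ((fv * (1 - e))[-1] + (fv * (1 - e))[-length(e)]) / 2)
      }
      D <- mean(Ds)
      if (D <= 0) return(Inf)
      x_eti + xx * mean(Ns) / D
    }
  }, numeric(1))
}

#' Limit of the endemic function at zero infection pressure
#'
#' `lim_{x -> 0} F_e(x) = 1 / Sigma`, evaluated directly from the
#' stationary susceptibility rather than by substituting a tiny `x`
#' (which cancels catastrophically).
#'
#' @param spec A [model_spec()].
#' @return A number `>= 1`, possibly `Inf`.
#' @export
endemic_function_limit <- function(spec) {
  endemic_threshold(spec)
}

#' Find the endemic equilibria of a model
#'
#' Scans the endemic function on a logarithmic grid up to the a-priori root
#' bound `x <= R0 / E[T_I]`, brackets every sign change of `F_e - R0` and
#' refines each root by bisection.  Each root `x` yields an equilibrium
#' with boundary values `I(0) = x / R0`,
#' `S(0) = I(0) / E[1 - e^{-x phi(T_V)}]`, age profiles along the
#' stationary characteristics, prevalence `I(0) E[T_I]` (the endemic
#' level `x E[T_I] / R0`).
#'
#' An empty result is a valid answer: for deterministic and step
#' susceptibility laws it is equivalent to `R0 * Sigma <= 1`.
#'
#' @param r0 Basic reproduction number at which to solve (defaults to the
#'   spec's own).
#' @param spec A [model_spec()].
#' @param ages Age grid for the returned profiles.
#' @param n_grid Number of scan points.
#' @param x_min Lower end of the scan.
#' @return A tibble with one row per equilibrium: `x`, `I0`, `S0`,
#'   `prevalence`, `endemic_level` and a `profile` list-column of
#'   `(a, I, S)` tibbles.
#' @export
find_endemic_equilibria <- function(r0, spec, ages = NULL, n_grid = 400L,
                                    x_min = 1e-8) {
  stopifnot(inherits(spec, "model_spec"), r0 > 0)
  eti <- law_mean(spec$infectiousness$duration)
  x_max <- r0 / eti
  xs <- exp(seq(log(x_min), log(x_max), length.out = n_grid))
  fe <- endemic_function(xs, spec) - r0
  roots <- numeric(0)
  sgn <- sign(fe)
  for (i in seq_len(n_grid - 1L)) {
    if (is.finite(fe[i]) && is.finite(fe[i + 1]) && sgn[i] * sgn[i + 1] < 0) {
      rt <- stats::uniroot(function(z) endemic_function(z, spec) - r0,
                           c(xs[i], xs[i + 1]), tol = 1e-10)$root
      roots <- c(roots, rt)
    } else if (is.finite(fe[i]) && fe[i] == 0) {
      roots <- c(roots, xs[i])
    }
  }
  if (any(diff(sign(diff(fe[is.finite(fe)]))) != 0)) {
    message("endemic function scan is not monotone; reporting all roots")
  }
  if (length(roots) == 0) {
    return(tibble::tibble(x = numeric(0), I0 = numeric(0), S0 = numeric(0),
                          prevalence = numeric(0),
                          endemic_level = numeric(0), profile = list()))
  }
  if (is.null(ages)) {
    aup <- max(law_upper(spec$infectiousness$duration),
               if (spec$vaccination$is_infinite) 10 * eti else
                 law_upper(spec$vaccination))
    ages <- seq(0, aup, length.out = 512L)
  }
  rows <- purrr::map_dfr(roots, function(x) {
    prof <- equilibrium_profile(x, r0, spec, ages)
    tibble::tibble(x = x, I0 = x / r0, S0 = prof$S0,
                   prevalence = (x / r0) * eti,
                   endemic_level = (x / r0) * eti,
                   profile = list(prof$tab))
  })
  rows
}

# Age profiles of the equilibrium with pressure x: I(a) = I(0) S_TI(a),
# S(a) = S(0) S_TV(a) E[e^{-x phi(a)}].
equilibrium_profile <- function(x, r0, spec, ages, n_nodes = 512L) {
  sus <- spec$susceptibility
  vac <- spec$vaccination
  I0 <- x / r0
  Eexp <- switch(sus$kind,
    deterministic = {
      ph <- make_phi(sus, a_hint = max(ages))
      exp(-x * ph$phi(ages))
    },
    step = {
      r <- tr_nodes(sus$recovery, n_nodes)
      vapply(ages, function(a) mean(exp(-x * pmax(a - r, 0))), numeric(1))
    },
    panel = {
      grid_v <- vapply(sus$curves, function(f) {
        sg <- f(ages)
        ph <- c(0, cumsum(diff(ages) * (sg[-1] + sg[-length(sg)]) / 2))
        exp(-x * ph)
      }, numeric(length(ages)))
      rowMeans(grid_v)
    })
  # D = E[1 - e^{-x phi(T_V)}] via the same representation
  D <- switch(sus$kind,
    step = {
      r <- tr_nodes(sus$recovery, n_nodes)
      if (vac$is_infinite) mean(is.finite(r)) else {
        pW <- function(w) vapply(w, function(ww) {
          mean(law_survival(vac, r + ww))
        }, numeric(1))
        stats::integrate(function(w) x * exp(-x * w) * pW(w), 0,
                         min(law_upper(vac), 746 / x), rel.tol = 1e-12,
                         subdivisions = 2000L, stop.on.error = FALSE)$value
      }
    },
    {
      # deterministic / panel: D = E[1 - e^{-x phi(T_V)}] by quadrature
      Ee_at <- function(aa) {
        if (sus$kind == "deterministic") {
          ph <- make_phi(sus, a_hint = max(aa, max(ages)))
          exp(-x * ph$phi(aa))
        } else {
          m <- vapply(sus$curves, function(f) {
            gr <- seq(0, max(aa), length.out = 2048L)
            sg <- f(gr)
            ph <- c(0, cumsum(diff(gr) * (sg[-1] + sg[-length(sg)]) / 2))
            stats::approx(gr, exp(-x * ph), xout = aa)$y
          }, numeric(length(aa)))
          if (length(aa) == 1L) mean(m) else rowMeans(m)
        }
      }
      if (vac$is_infinite) {
        if (sigma_limit(sus) > 0) 1 else 1 - Ee_at(1e8)
      } else if (vac$is_point_mass) {
        1 - Ee_at(law_mean(vac))
      } else {
        up <- law_upper(vac)
        gr <- seq(0, up, length.out = 4096L)
        iv <- law_density(vac, gr) * (1 - Ee_at(gr))
        sum(diff(gr) * (iv[-1] + iv[-length(iv)]) / 2)
      }
    })
  S0 <- I0 / D
  tab <- tibble::tibble(
    a = ages,
    I = I0 * law_survival(spec$infectiousness$duration, ages),
    S = S0 * law_survival(vac, ages) * Eexp)
  list(tab = tab, S0 = S0, D = D)
}

#' Build a model specification started at an endemic equilibrium
#'
#' Computes the (first) endemic equilibrium of `spec` and returns a new
#' spec whose initial fraction and age densities are the equilibrium
#' profiles, so that the deterministic limit should stay put.  Exact
#' stationarity of the initial condition is only representable for a
#' deterministic susceptibility curve (for random curves the equilibrium
#' age profile carries an exposure-tilted curve distribution that the
#' unconditioned initial draw cannot encode).
#'
#' @param spec A [model_spec()] with deterministic susceptibility.
#' @return A `model_spec`.
#' @export
initialize_at_equilibrium <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$susceptibility$kind != "deterministic") {
    stop(paste("equilibrium initialization is exact only for deterministic",
               "susceptibility curves"), call. = FALSE)
  }
  eq <- find_endemic_equilibria(spec$r0, spec)
  if (nrow(eq) == 0) {
    stop("no endemic equilibrium exists for this spec", call. = FALSE)
  }
  prof <- eq$profile[[1]]
  i0 <- eq$prevalence[1]
  model_spec(spec$infectiousness, spec$susceptibility, spec$vaccination,
             i0 = i0,
             h_i = grid_law(prof$a, prof$I),
             h_s = grid_law(prof$a, prof$S))
}
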