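---
title: "Models and methods in waningvax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in waningvax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`waningvax` studies a closed population of `N` individuals that cycle
between an infectious state and a susceptible state.  On infection an
individual draws an infectiousness curve `lambda(a)` on a random
infectious period `T_I`; while infectious its susceptibility is 0.  On
recovery, and again at every vaccination, it draws a fresh non-decreasing
susceptibility curve `sigma(a)` with values in `[0, 1]` — `a` is the
*class age*, the time since the last event — and is vaccinated recurrently
at renewal intervals `T_V` until reinfected.  Reinfection occurs at rate
`sigma_i(t) * Lambda(t)` with `Lambda(t) = mean_i lambda_i(t)` the force
of infection.  Vaccination and natural infection are assumed to reset
immunity in the same way, individual curves are drawn independently of
everything drawn before (no immune memory across cycles), and the
susceptibility drawn after an infection is independent of the
infectiousness during it.  These independence assumptions are what make
the vaccination process of an undisturbed individual a renewal process,
and they are the load-bearing assumptions of the whole equilibrium
analysis.

The initial condition assumes the epidemic and the vaccination programme
have been running for a while: a fraction `i0` is infectious with class
ages from a density `h_i` (infectiousness conditioned on `T_I` exceeding
the age), the rest susceptible with ages from `h_s` (curve drawn
unconditionally, residual booster time conditioned to exceed the age).
By default `h_i` and `h_s` are the stationary residual-age laws of `T_I`
and `T_V` (`residual_law()`), which are always compatible with that
conditioning.

## Built-in law families, and what they do not capture

Duration laws: exponential, gamma, uniform, point mass, two-point
mixtures, optional shifts, and an infinite sentinel that switches
vaccination off (yielding the SIR/SIS/SIRS reductions).  Susceptibility
kinds: a deterministic curve (notably `sigma_gamma_cdf()`, a Gamma CDF in
age — protection plateaus, then is lost around `shape * scale`), a step
curve `1(a >= T_R)` with random immune window `T_R`, and a finite panel
of curves materialized once from a seeded sampler and reused everywhere,
so that derived functionals are smooth in their arguments (common random
numbers stabilize root-finding).

The reference parameterization `default_model_spec()` is in days:
Gamma(2, 3.5) infectious periods (mean one week), Gamma-CDF
susceptibility with shape 4 and scale 45 and Gamma(4, 45) boosters (both
around six months).  These are the package's own choices of plausible
magnitudes, not estimates for any particular pathogen.  The generator
emulates waning immunity, recurrent boosting and heterogeneous uptake; it
does not emulate demographic turnover, seasonality, pathogen evolution,
behavioural feedback, or correlation between disease severity and
subsequent immunity — conclusions from passing tests are claims about the
model class, not about any real epidemic.

## The deterministic limit and its solver

As `N` grows the empirical age measures converge to densities `I(t, a)`,
`S(t, a)` solving age-structured transport equations with removal rates
given by the hazards of `T_I` and `T_V` and an infection term
`Lambda(t) * E_{t,a}[sigma(a)]`.  Crucially, when `sigma` is random the
limit retains a conditioning term:

    E_{t,a}[sigma(a)] = E[sigma(a) exp(-int_0^a Lambda(t-a+u) sigma(u) du)] /
                        E[exp(-int_0^a Lambda(t-a+u) sigma(u) du)]

— a susceptible that has survived exposure is biased toward low
susceptibility.  `exposure_weighted_susceptibility()` computes this
quantity directly; the bias vanishes for deterministic curves and at zero
exposure.

Rather than discretizing the transport PDE, the solver integrates the
equivalent Volterra system for the boundary fluxes `x(t) = I(t, 0)`,
`y(t) = S(t, 0)` and the force `L(t)`, and reconstructs the densities
along characteristics.  One wrinkle: written purely as convolutions
against the *unconditional* mean curve `E[lambda(a)]`, the contribution
of the initially infected requires the factor `1 / P(T_I > age)` that
undoes the initial conditioning; the solver carries that factor in the
initial cohort weights so that the force of infection, the recovery flux
and the prevalence of the initial cohorts are mutually consistent with
the transport form.

Numerical scheme (all choices are the package's own; no scheme is
prescribed by the theory):

* Uniform time grid of step `dt` (also the age resolution), trapezoidal
  convolution rules, and per-step Picard iteration to `1e-10` (cap 200;
  failure suggests a smaller `dt`).  `dt` must satisfy
  `lambda_max * dt < 0.1`.
* Removal kernels are represented by **cell-averaged densities**: the
  exact probability mass of each age cell, read off the survival
  function, with survival grids rebuilt as the running trapezoidal
  integral of the discrete density.  This makes the discrete kernel mass
  telescope to one for *every* law — uniform edges, shifted supports, and
  point masses (split over their two neighbouring cells, preserving the
  first moment) included — which is what keeps total mass conserved at
  second order; sampling the density at nodes instead leaves O(dt)
  conservation drift for non-smooth laws.
* The exposure exponent of every birth cohort is maintained
  incrementally.  For curve-type susceptibility each panel member carries
  its own integral; for step curves a random `T_R` is represented by
  `n_step_nodes = 256` quantile-midpoint atoms and each cohort stores a
  single running sum over crossed thresholds, kept relative to the
  cumulative force so no exponential ever overflows — O(1) work per
  cohort per step.  Threshold crossings inside the current step are
  included in the infection flux (ignoring them leaves O(dt) drift), and
  an explicit correction term repairs the trapezoidal mislocation of the
  staircase jumps of `E[sigma e^{-Q}]` within their cells.
* Initial age densities are discretized into `init_cohorts = 1024`
  equal-mass quantile cohorts, so initial mass is exact by construction;
  reconstructed initial densities are therefore atom trains and should be
  compared through bin masses, not pointwise.
* Age integrals are truncated at the `1 - 1e-8` quantile of the relevant
  law; cohorts are pruned once both their survival and removal density
  vanish below `1e-14`.
* Diagnostics after every solve: the conserved total mass (error beyond
  `mass_tol` aborts) and the a-priori bound `x(t) <= Lambda(t)`.

Measured behaviour (asserted by the test suite): mass drift is at the
`1e-5` level for `dt = 0.01` over 100 time units across the built-in
families, halving `dt` shrinks the solution error, the SIRS reduction
matches an independently integrated ODE to a few `1e-4`, and a solution
started at a computed endemic equilibrium stays put to `1e-5`.

The multigroup solver is the same machinery with per-group fluxes and the
coupled force `sum_l' gamma(l',l) Lambda_l'`; groups collapse exactly onto
the homogeneous solution when vaccination and activity are equal.

## The stochastic simulator

The finite-`N` model is simulated exactly by event-driven thinning.
Recoveries and vaccinations sit in a priority queue at their
pre-scheduled times (ties broken recovery < vaccination < infection, then
by index, for deterministic replay).  Infection candidates are proposed
at a bounding rate — exact (`Lambda` itself) for constant transmission
rates, `lambda_max * #I / N` for profiled curves — and accepted with
probability `sigma_i(t) * Lambda(t) / bound`; the bound is piecewise
constant between events, so exponential waiting times are valid proposals.
All randomness flows from R's RNG, so `set.seed()` makes runs
bit-identical; replicate runs derive sub-seeds from the user seed.  The
simulator's first-infection law matches the analytic survival
`exp(-Lambda_bar * Phi(a))` (Kolmogorov-Smirnov test), and replicate
means track the deterministic limit within Monte-Carlo error at
`N = 8000`.

Age-conditioned initial draws use inverse-CDF restriction, which is exact
and needs no rejection loop; ages outside the support of the conditioning
law are an error.

## Equilibrium computation

`endemic_function()` evaluates `F_e` by adaptive quadrature for
deterministic curves (with `Phi` tabulated once by cumulative Simpson and
spline-interpolated), by panel averages for panels, and by a closed form
for step curves — with the generic quadrature retained as an independent
cross-check, the two agreeing to ~1e-9.  The `x -> 0` limit `1/Sigma` is
exposed separately (`endemic_threshold()`) because evaluating the ratio
at tiny `x` cancels catastrophically.  `find_endemic_equilibria()` scans
400 log-spaced points up to the a-priori bound `x <= R0 / E[T_I]`,
bisects every bracket to `1e-10`, and reports *all* roots: monotonicity
of `F_e` is only established for deterministic and step curves, so a
non-monotone scan is flagged rather than silently truncated.  Profiles
come from the stationary characteristics, and their total mass integrates
to one.

`initialize_at_equilibrium()` is restricted to deterministic curves: at
an equilibrium with random curves the age profile carries an
exposure-tilted curve distribution that the model's unconditioned initial
draw cannot represent, so exact stationarity is not expressible through
the initial condition alone.

## Multigroup choices

The spectral radius uses power iteration with Perron normalization; the
stopping rule bounds the true error through the estimated convergence
ratio and Aitken-extrapolates, so slow spectra still reach `1e-13`-level
agreement with the closed-form two-group root.  Reducible contact
matrices are accepted by `group_model()` (isolated groups are a useful
degenerate case for the solver) but refused by `next_generation()`,
whose branching-process justification needs irreducibility.  At the
endpoints of the fair-allocation family one group is unvaccinated; its
stationary susceptibility is taken as the long-age limit of the mean
curve, i.e. 1 under full waning.

## Problem sizes used by the shipped tests

The acceptance-style tests run at desk scale, chosen to finish in minutes
on one core: conservation on 5 randomized specifications at `dt = 0.01`
over 100 time units; the bifurcation sweep on 12 reproduction numbers to
`t = 300` at `dt = 0.025`; mean-field convergence with 20 replicates at
`N` in {500, 2000, 8000}; Monte-Carlo oracles with `1e6` draws.  Fast
within-host-free time units (mean infectious period = 1) are used
throughout the tests so that long-time behaviour is reached quickly.

## Known limitations

* Panel susceptibility in the solver costs O(T/dt * K) memory and time
  per step; large panels with fine grids are rejected with a message.
  The simulator's panel path is cheap.
* Atom booster laws are placed on the age grid to within `dt/2` (split
  across two cells, first moment exact); dynamics are second-order
  accurate but atoms narrower than a cell cannot be represented more
  finely than the grid.
* The endemic threshold under *no* vaccination is the large-age limit of
  the mean susceptibility, reached through the infinite sentinel with a
  warning; the interchange of limits behind this convention is a modelling
  choice, exercised by the large-`T_V` tests.
* Stability of equilibria is probed numerically (long-time integration),
  not proved.
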