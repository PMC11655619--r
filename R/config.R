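#' Read a model specification from a YAML file
#'
#' The configuration has blocks `infectiousness`, `susceptibility`,
#' `vaccination` and `initial`, plus optional `r0`, `numerics` (grid step,
#' horizon, seed) and `groups` (multigroup extension).  Unknown keys are
#' rejected so that typos do not silently fall back to defaults.
#'
#' Duration laws are written as `{family: gamma, shape: 4, scale: 45}`;
#' `family: none` (or `infinite`) is the no-vaccination sentinel.
#' Susceptibility kinds: `gamma_cdf` (`shape`, `scale`), `constant`
#' (`value`), `step` (`recovery:` a duration law).
#'
#' @param path Path to a YAML file.
#' @return A list of class `waningvax_config` with elements `spec` (a
#'   [model_spec()]), `numerics` (list with `dt`, `tmax`, `seed`) and
#'   `groups` (a [group_model()] or `NULL`).
#' @export
read_model_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("infectiousness", "susceptibility", "vaccination", "initial",
             "r0", "numerics", "groups")
  check_keys(cfg, known, "top level")
  for (blk in c("infectiousness", "susceptibility", "vaccination")) {
    if (is.null(cfg[[blk]])) {
      stop(sprintf("configuration block '%s' is missing", blk), call. = FALSE)
    }
  }

  inf_cfg <- cfg$infectiousness
  check_keys(inf_cfg, c("kind", "rate", "duration"), "infectiousness")
  kind <- inf_cfg$kind %||% "constant"
  if (kind != "constant") {
    stop("only 'constant' infectiousness curves can be written in YAML",
         call. = FALSE)
  }
  inf <- infectiousness_law("constant", rate = inf_cfg$rate,
                            duration = parse_duration(inf_cfg$duration,
                                                      "infectiousness$duration"))

  sus_cfg <- cfg$susceptibility
  check_keys(sus_cfg, c("kind", "shape", "scale", "value", "recovery"),
             "susceptibility")
  sus <- switch(sus_cfg$kind %||% stop("susceptibility$kind is required",
                                       call. = FALSE),
    gamma_cdf = sigma_gamma_cdf(sus_cfg$shape, sus_cfg$scale),
    constant = sigma_constant(sus_cfg$value),
    step = susceptibility_law("step",
                              recovery = parse_duration(sus_cfg$recovery,
                                                        "susceptibility$recovery")),
    stop(sprintf("unknown susceptibility kind '%s'", sus_cfg$kind),
         call. = FALSE))

  vac <- parse_duration(cfg$vaccination, "vaccination")

  init <- cfg$initial %||% list()
  check_keys(init, c("i0", "h_i", "h_s"), "initial")
  h_i <- if (!is.null(init$h_i)) parse_duration(init$h_i, "initial$h_i")
  h_s <- if (!is.null(init$h_s)) parse_duration(init$h_s, "initial$h_s")

  spec <- model_spec(inf, sus, vac, i0 = init$i0 %||% 0.1,
                     h_i = h_i, h_s = h_s, r0 = cfg$r0)

  num <- cfg$numerics %||% list()
  check_keys(num, c("dt", "tmax", "seed"), "numerics")
  numerics <- list(dt = num$dt %||% 0.05, tmax = num$tmax %||% 100,
                   seed = num$seed %||% 1L)

  groups <- NULL
  if (!is.null(cfg$groups)) {
    g <- cfg$groups
    check_keys(g, c("p", "alpha", "gamma", "vaccination"), "groups")
    vlaws <- lapply(seq_along(g$vaccination), function(i) {
      parse_duration(g$vaccination[[i]], sprintf("groups$vaccination[%d]", i))
    })
    contact <- if (!is.null(g$gamma)) {
      do.call(rbind, g$gamma)
    } else if (!is.null(g$alpha) && length(g$p) == 2L) {
      two_group_contact_matrix(g$p[1], g$alpha)
    } else {
      stop("groups need either 'gamma' or (two groups and) 'alpha'",
           call. = FALSE)
    }
    groups <- group_model(p = unlist(g$p), contact = contact,
                          vaccination = vlaws,
                          infectiousness = spec$infectiousness,
                          susceptibility = spec$susceptibility)
  }

  structure(list(spec = spec, numerics = numerics, groups = groups),
            class = "waningvax_config")
}

parse_duration <- function(x, where) {
  if (is.null(x) || is.null(x$family)) {
    stop(sprintf("%s: a duration law needs a 'family'", where), call. = FALSE)
  }
  fam <- x$family
  if (fam %in% c("none", "infinite")) return(duration_law("infinite"))
  allowed <- switch(fam,
    exponential = c("rate"),
    gamma = c("shape", "scale"),
    uniform = c("min", "max"),
    point = c("value"),
    stop(sprintf("%s: unknown duration family '%s'", where, fam),
         call. = FALSE))
  check_keys(x, c("family", allowed, "shift"), where)
  args <- x[names(x) %in% c(allowed, "shift")]
  do.call(duration_law, c(list(family = fam), args))
}

check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
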