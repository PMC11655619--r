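#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.limit_solution <- function(x, ...) x$tab

#' @export
glance.limit_solution <- function(x, ...) {
  tibble::tibble(
    dt = x$dt, tmax = x$tmax,
    final_prevalence = utils::tail(x$tab$prevalence, 1),
    final_Lambda = utils::tail(x$tab$Lambda, 1),
    mass_drift = x$mass_drift,
    r0 = x$spec$r0,
    threshold = endemic_threshold(x$spec))
}

#' @export
tidy.multigroup_solution <- function(x, ...) x$tab

#' @export
glance.multigroup_solution <- function(x, ...) {
  tibble::tibble(
    dt = x$dt, tmax = x$tmax,
    final_prevalence = utils::tail(x$total$prevalence, 1),
    mass_drift = x$mass_drift)
}

#' @export
tidy.next_gen <- function(x, ...) {
  L <- length(x$Sigma)
  tibble::tibble(group = seq_len(L), Sigma = x$Sigma,
                 rho = rep(x$rho, L))
}

#' @export
glance.next_gen <- function(x, ...) {
  tibble::tibble(rho = x$rho,
                 r0_rho = x$r0_rho %||% NA_real_,
                 endemic = x$endemic %||% NA)
}

#' @export
autoplot.limit_solution <- function(object, ...) {
  d <- tidyr::pivot_longer(object$tab[, c("t", "prevalence",
                                          "susceptible_mass")],
                           -"t", names_to = "series")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "population fraction", colour = NULL)
}

#' @export
autoplot.multigroup_solution <- function(object, ...) {
  ggplot2::ggplot(object$tab,
                  ggplot2::aes(x = .data$t, y = .data$prevalence,
                               colour = factor(.data$group))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "prevalence", colour = "group")
}

#' @export
autoplot.ibm_trajectory <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t, y = .data$prevalence,
                               group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time", y = "prevalence")
}

#' Plot a bifurcation sweep
#'
#' Terminal prevalence against the basic reproduction number with the
#' analytic endemic threshold as a dashed line.
#'
#' @param tab Output of [run_bifurcation()].
#' @return A ggplot.
#' @export
plot_bifurcation <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$r0,
                                    y = .data$terminal_prevalence)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(R[0]), y = "terminal prevalence")
}

#' Plot an allocation scan
#'
#' The endemic threshold `1/rho` against the fairness parameter, one curve
#' per contact parameter.
#'
#' @param tab Output of [run_allocation_scan()] / [fair_allocation()].
#' @return A ggplot.
#' @export
plot_allocation <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$beta, y = .data$inv_rho,
                                    colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(beta), y = expression(1 / rho),
                  colour = expression(alpha))
}

#' @importFrom rlang .data
NULL
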