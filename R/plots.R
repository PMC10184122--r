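#' Plot a PMF profile
#'
#' Free-energy profile versus donor--acceptor distance, with a
#' `+- 1 sd` bootstrap ribbon when the profile carries errors.
#'
#' @param object a `pmf_profile` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$distance,
                                            y = .data$pmf))
  if ("sd" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pmf - .data$sd,
                   ymax = .data$pmf + .data$sd),
      alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "donor-acceptor distance (Å)",
                  y = "PMF (kcal/mol)")
}

#' Plot a work-profile ensemble
#'
#' One translucent line per steered trajectory.
#'
#' @param object a `work_ensemble` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.work_ensemble <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$work,
                                       group = .data$traj_id)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::labs(x = "guide distance (Å)", y = "work (kcal/mol)")
}

#' Plot a radial distribution function
#'
#' @param object an `rdf_profile` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rdf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "r (Å)", y = "g(r)")
}

#' Plot a rupture-total versus binding-affinity correlation
#'
#' Scatter of per-complex summed rupture free energies against binding
#' free energies with the least-squares line and complex labels.
#'
#' @param object an `affinity_correlation`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.affinity_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$total,
                                            y = .data$dg_bin)) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$complex),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = expression(Sigma * "PMF (kcal/mol)"),
      y = expression(Delta * G[bin] ~ "(kcal/mol)"),
      subtitle = sprintf("R² = %.2f (n = %d)",
                         object$r_squared, object$n))
}

#' Plot a saturation-binding fit
#'
#' Titration points on a log concentration axis with the fitted one-site
#' isotherm and the half-saturation point at `K_D`.
#'
#' @param object a `binding_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.binding_fit <- function(object, ...) {
  rng <- range(object$data$concentration)
  grid <- tibble(
    concentration = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200))
  grid$signal <- object$y_max * grid$concentration /
    (object$k_d + grid$concentration)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$concentration,
                                            y = .data$signal)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_d, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand concentration (M)", y = "signal",
                  subtitle = sprintf("K_D = %.3g M", object$k_d))
}
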