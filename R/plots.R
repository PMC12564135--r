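# ggplot2 autoplot methods for the package's result types.

#' Plot a 1-D profile
#'
#' @param object An `fr_profile` (density, distance distribution, ...).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fr_profile <- function(object, ...) {
  lab <- switch(attr(object, "mode"),
    probability_density = "probability density",
    number_density = expression(rho ~ (ring(A)^-3)),
    counts = "mean count per bin"
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "z (Å)", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a 2-D conformation / joint map
#'
#' @param object An `fr_density2d` from [conformation_map()] or
#'   [hbond_vs_z()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fr_density2d <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a forward-reverse PMF estimate
#'
#' Draws the estimated free-energy profile with a +-1 SE ribbon.
#'
#' @param object An `fr_pmf` from [estimate_pmf()].
#' @param true_potential Optional [potential()] overlaid (anchored the same
#'   way) for generator ground-truth comparison.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fr_pmf <- function(object, true_potential = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$dU)) +
    ggplot2::labs(x = "z (Å)", y = "ΔU (kcal/mol)") +
    ggplot2::theme_minimal()
  if (!all(is.na(object$se))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$dU - .data$se, ymax = .data$dU + .data$se),
      alpha = 0.25
    )
  }
  p <- p + ggplot2::geom_line()
  if (!is.null(true_potential)) {
    u <- pot_energy(true_potential, object$z)
    u <- u - approx(object$z, u, xout = attr(object, "anchor"))$y
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(z = object$z, dU = u),
      linetype = "dashed", colour = "red"
    )
  }
  p
}

#' Plot a work trace
#'
#' @param object An `fr_work_trace` from [simulate_smd_pull()].
#' @param ... Unused.
#' @return A ggplot of cumulative work against guide position.
#' @export
autoplot.fr_work_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda, y = .data$W)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "guide position λ (Å)",
                  y = "W (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a Langevin path
#'
#' @param object An `fr_path` from [simulate_langevin_1d()].
#' @param window Optional running-average window (samples) overlaid.
#' @param ... Unused.
#' @return A ggplot of z against time.
#' @export
autoplot.fr_path <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$z)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (ns)", y = "z (Å)") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(time = object$time,
                            z = running_average(object$z, window)),
      colour = "blue"
    )
  }
  p
}
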