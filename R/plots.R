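#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a theory sweep
#'
#' Enhancement against a chosen grid variable, with the gamma ceiling
#' overlaid.
#'
#' @param object a `kaeff_sweep` from [theory_sweep()] or
#'   [run_figure_regime()].
#' @param x name of the column to map to the x axis (defaults to the
#'   first swept column).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot kaeff_sweep
#' @export
autoplot.kaeff_sweep <- function(object, x = NULL, ...) {
  x <- x %||% names(object)[1]
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[x]], y = .data$enhancement)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gamma), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = x, y = expression(K[a]^eff / K[a]^PP),
                  subtitle = "dashed: geometric ceiling gamma") +
    ggplot2::theme_minimal()
  if ("ode_enhancement" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$ode_enhancement),
                                 colour = "red", shape = 1)
  }
  p
}

#' Plot a simulated trajectory
#'
#' Species concentrations against time (log-log).
#'
#' @param object a `kaeff_trajectory`.
#' @param species optional subset of species names.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot kaeff_trajectory
#' @export
autoplot.kaeff_trajectory <- function(object, species = NULL, ...) {
  long <- tidy.kaeff_trajectory(object)
  if (!is.null(species)) long <- dplyr::filter(long, .data$species %in% !!species)
  ggplot2::ggplot(dplyr::filter(long, .data$time > 0),
                  ggplot2::aes(x = .data$time, y = .data$conc,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = expression(concentration~(mu*m^-3))) +
    ggplot2::theme_minimal()
}

#' Plot bond counts of a stochastic run
#'
#' @param object a `ssa_result`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ssa_result
#' @export
autoplot.ssa_result <- function(object, ...) {
  ggplot2::ggplot(tidy.ssa_result(object),
                  ggplot2::aes(x = .data$time, y = .data$bonds,
                               colour = .data$rule)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "bonds") +
    ggplot2::theme_minimal()
}
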