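#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for stationary and simulation results
#'
#' `autoplot()` gives a ready ggplot for each result type: stationary
#' densities and distributions as lines over molecule number,
#' occupancy histograms as columns, trajectories as step functions,
#' phase diagrams as tiles (two axes) or stability profiles (one
#' axis), and extremum tracks as location-versus-burst-size branches.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name burstbif_autoplot
NULL

#' @rdname burstbif_autoplot
#' @export
autoplot.stationary_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "molecule number x", y = "stationary density Ps(x)",
                  title = paste0("Fokker-Planck stationary density (",
                                 attr(object, "method"), ", r = ",
                                 attr(object, "params")$r, ")"))
}

#' @rdname burstbif_autoplot
#' @export
autoplot.cme_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "molecule number x", y = "stationary probability p(x)",
                  title = paste0("Master-equation stationary distribution (r = ",
                                 attr(object, "params")$r, ")"))
}

#' @rdname burstbif_autoplot
#' @export
autoplot.occupancy_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "molecule number x", y = "occupancy fraction",
                  title = "Time-weighted occupancy histogram")
}

#' @rdname burstbif_autoplot
#' @export
autoplot.ssa_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$events, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (1/rate units)", y = "molecule number x",
                  title = paste0("Gillespie trajectory (r = ",
                                 object$params$r, ", x0 = ", object$x0, ")"))
}

#' @rdname burstbif_autoplot
#' @export
autoplot.phase_diagram <- function(object, ...) {
  axes <- attr(object, "axes")
  if (length(axes) == 2) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[axes[1]]],
                                         y = .data[[axes[2]]],
                                         fill = factor(.data$n_maxima))) +
      ggplot2::geom_tile() +
      ggplot2::facet_wrap(~r, labeller = ggplot2::label_both) +
      ggplot2::labs(fill = "maxima")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[axes[1]]],
                                         y = .data$n_maxima,
                                         colour = factor(.data$r))) +
      ggplot2::geom_step() +
      ggplot2::labs(colour = "burst size r", y = "stationary maxima")
  }
}

#' @rdname burstbif_autoplot
#' @export
autoplot.extrema_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$location,
                                       shape = .data$type,
                                       colour = .data$type)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "burst size r", y = "extremum location (molecules)",
                  title = "Stationary extrema versus burst size")
}
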