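# ggplot2 quick-look methods for the result containers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a simulated trajectory
#'
#' Time courses of the dimensionless states on a log time axis (the
#' boundary layer and the slow depletion differ by orders of magnitude).
#'
#' @param object A `ciket_trajectory`.
#' @param vars State columns to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ciket_trajectory <- function(object,
                                      vars = c("S", "I", "E", "X", "Y", "P"),
                                      ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "tau",
                  dplyr::all_of(vars)),
    -"tau", names_to = "state", values_to = "value")
  df <- dplyr::filter(df, .data$tau > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$tau, .data$value,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau), y = "dimensionless level",
                  colour = NULL,
                  title = paste0(attr(object, "scheme"),
                                 " scheme trajectory")) +
    ggplot2::theme_minimal()
}

#' Phase-plane section of a trajectory
#'
#' @param traj A `ciket_trajectory`.
#' @param x,y Column names (default the velocity-substrate section).
#' @return A ggplot.
#' @export
plot_phase <- function(traj, x = "S", y = "V") {
  ggplot2::ggplot(tibble::as_tibble(traj),
                  ggplot2::aes(.data[[x]], .data[[y]])) +
    ggplot2::geom_path() +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
}

#' Heat map of an error grid
#'
#' @param object A `ciket_error_grid` from [error_grid()].
#' @param which Error column to draw (default the first one).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ciket_error_grid <- function(object, which = NULL, ...) {
  errs <- grep("^err", names(object), value = TRUE)
  which <- which %||% errs[1]
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$eps_S, .data$eps_I,
                               fill = log10(.data[[which]]))) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(epsilon[S]), y = expression(epsilon[I]),
                  fill = paste0("log10 ", which)) +
    ggplot2::theme_minimal()
}

#' Observed versus fitted velocities
#'
#' @param object A `ciket_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ciket_fit <- function(object, ...) {
  df <- tibble::tibble(observed = object$data$v,
                       fitted = fitted(object),
                       i0 = factor(object$data$i0))
  ggplot2::ggplot(df, ggplot2::aes(.data$fitted, .data$observed,
                                   colour = .data$i0)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fitted v", y = "observed v",
                  colour = expression(i[0])) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
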