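# ggplot2 visualisations

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot time-activity curves
#'
#' @param tacs Long framed TAC tibble (from [simulate_subject()]'s `tacs`
#'   or [read_tac_table()]).
#' @param log_y Log-scale the activity axis.
#' @return A ggplot.
#' @export
plot_tacs <- function(tacs, log_y = FALSE) {
  stopifnot(is.data.frame(tacs))
  p <- ggplot2::ggplot(tacs, ggplot2::aes(x = .data$mid, y = .data$value,
                                          colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "time (s)", y = paste0("activity (", tacs$units[1], ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn plot_tacs Measured curve with its parametric fit overlaid.
#' @param object A `feng_fit`.
#' @param ... Unused.
#' @export
autoplot.feng_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(data = object$fitted, colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "activity",
                  subtitle = sprintf("residual RMS %.3g", object$rms)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tcm_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = object$fitted, colour = "steelblue") +
    ggplot2::labs(x = "frame mid-time (s)", y = "tissue activity",
                  subtitle = sprintf("K1 %.3g, k2 %.3g, k3 %.3g, k4 %.3g, vB %.3g",
                                     object$params$K1, object$params$k2,
                                     object$params$k3, object$params$k4,
                                     object$params$vB)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.patlak_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "normalised time (s)", y = "tissue / plasma",
                  subtitle = sprintf("Ki %.4g ml/min/ml, r2 %.4f",
                                     object$Ki_patlak, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pet_subject <- function(object, ...) {
  aif <- dplyr::mutate(object$aif_true, what = "true AIF")
  trc <- dplyr::mutate(object$trace, what = "detector trace")
  ggplot2::ggplot(dplyr::bind_rows(aif, trc),
                  ggplot2::aes(x = .data$time, y = .data$value,
                               colour = .data$what)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::rename(object$samples,
                                             value = "concentration"),
                        ggplot2::aes(x = .data$time, y = .data$value),
                        inherit.aes = FALSE, shape = 4, size = 2) +
    ggplot2::labs(x = "time (s)", y = "activity", colour = NULL) +
    ggplot2::theme_minimal()
}
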