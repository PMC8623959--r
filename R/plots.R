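#' Plot a vibration record
#'
#' @param object An `lrfa_record`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lrfa_record <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Voltage (a.u.)",
                  title = attr(object, "record_id")) +
    ggplot2::theme_minimal()
}

#' Plot an amplitude spectrum, optionally with analysis bands
#'
#' @param object An `lrfa_spectrum`.
#' @param bands Optional [band_scheme()] whose edges are drawn as dashed
#'   lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lrfa_spectrum <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$frequency_hz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    edges <- sort(unique(c(bands$low_hz, bands$high_hz)))
    p <- p + ggplot2::geom_vline(xintercept = edges, linetype = "dashed",
                                 colour = "grey50", linewidth = 0.3)
  }
  p
}

#' Plot bootstrap-Lasso selection counts
#'
#' Bar chart of selection counts for the top-ranked explanatory variables.
#'
#' @param object An `lrfa_selection`.
#' @param top Number of variables shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lrfa_selection <- function(object, top = 20, ...) {
  df <- utils::head(tidy(object), top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$variable, -.data$n_selected),
                                   y = .data$n_selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Number of selections") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot predicted versus true torque with the ±20% accuracy band
#'
#' Scatter of predicted against true torque with the identity line (solid)
#' and the ±20% band (dashed) used as the clinical-usefulness criterion.
#'
#' @param object An `lrfa_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lrfa_evaluation <- function(object, ...) {
  pts <- object$points
  lim <- range(c(pts$true, pts$predicted))
  line <- tibble::tibble(x = seq(lim[1], lim[2], length.out = 50))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$true, y = .data$predicted)) +
    ggplot2::geom_line(data = line, ggplot2::aes(x = .data$x, y = .data$x),
                       inherit.aes = FALSE) +
    ggplot2::geom_line(data = line, ggplot2::aes(x = .data$x, y = 1.2 * .data$x),
                       linetype = "dashed", inherit.aes = FALSE) +
    ggplot2::geom_line(data = line, ggplot2::aes(x = .data$x, y = 0.8 * .data$x),
                       linetype = "dashed", inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$within_20pct)) +
    ggplot2::labs(x = "Measured peak torque (Nm)",
                  y = "Predicted peak torque (Nm)", colour = "Within 20%") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
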