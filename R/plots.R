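#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force-extension trace
#'
#' @param object An `fe_trace`.
#' @param events Optional [detect_events()] table to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fe_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$extension_nm,
                                            y = .data$force_pN)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.8) +
    ggplot2::labs(x = "extension (nm)", y = "force (pN)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    pts <- object[events$index, ]
    p <- p + ggplot2::geom_point(data = pts, colour = "red", shape = 1, size = 2)
  }
  p
}

#' Plot a contour-length series and its histogram
#'
#' @param object A `contour_length_series`.
#' @param bin_width Histogram bin width, nm.
#' @param ... Unused.
#' @return A ggplot (histogram of contour lengths).
#' @export
autoplot.contour_length_series <- function(object, bin_width = 0.75, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$contour_nm)) +
    ggplot2::geom_histogram(binwidth = bin_width, fill = "grey60",
                            colour = "grey30") +
    ggplot2::labs(x = "contour length (nm)", y = "samples") +
    ggplot2::theme_minimal()
}

#' Plot a pair-distance distribution p(r)
#'
#' @param object A `distance_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_distribution <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$mid <- (d$r_lo + d$r_hi) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "p(r) (pair counts)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted peak set over its histogram
#'
#' @param object A `peak_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peak_set <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70",
                      width = diff(h$mid[1:2])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black") +
    ggplot2::geom_vline(xintercept = object$peaks$mean_nm, linetype = 3) +
    ggplot2::labs(x = "contour length (nm)", y = "samples") +
    ggplot2::theme_minimal()
}
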