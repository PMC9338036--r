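# Optional figures.  ggplot2 is suggested, not imported; the functions fail
# gracefully with a clear message when it is unavailable.

#' Scatter, class means and loess curve along one gradient
#'
#' Species-level DCWL against a gradient variable, with the class-binned
#' means overplotted and the loess curve fitted to those means.
#'
#' @inheritParams gradient_curve
#' @return A ggplot object.
#' @export
plot_gradient <- function(samples, var, bin_width = NULL, origin = 0,
                          span = 0.75, degree = 2, value = "dcwl") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the 'ggplot2' package is required for plotting", call. = FALSE)
  }
  gc <- gradient_curve(samples, var, bin_width, origin, span, degree, value)
  df <- data.frame(x = samples[[var]], y = samples[[value]])
  bins <- as.data.frame(gc$bins)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.25, colour = "grey55", size = 0.8) +
    ggplot2::geom_point(data = bins,
                        ggplot2::aes(x = .data$bin_center, y = .data$mean_y),
                        colour = "black", size = 1.6) +
    ggplot2::labs(x = var, y = "DCWL") +
    ggplot2::theme_minimal()
  if (!is.null(gc$loess)) {
    curve <- data.frame(x = gc$loess$x, y = gc$loess$fitted)
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "red", linewidth = 0.9)
  }
  p
}
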