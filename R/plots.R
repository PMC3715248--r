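# ggplot2 visualisation layer: label maps in the fixed class palette, ROC
# scatter on percentage axes, confusion heatmap, signature spectra.

palette_hex <- function() {
  pal <- class_palette()
  stats::setNames(grDevices::rgb(pal$r, pal$g, pal$b, maxColorValue = 255),
                  pal$class)
}

#' @describeIn label_map Plot a label map in the fixed class palette.
#' @param object A `vineseg_label_map`.
#' @param ... Unused.
#' @method autoplot vineseg_label_map
#' @export
autoplot.vineseg_label_map <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    class = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = palette_hex(), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' @describeIn confusion Heatmap of the matching matrix.
#' @param object A `vineseg_confusion`.
#' @method autoplot vineseg_confusion
#' @export
autoplot.vineseg_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "grey20",
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted", y = "truth") +
    ggplot2::theme_minimal()
}

#' ROC scatter of per-class, per-scene operating points
#'
#' One point per class per scene on \[0,100\] axes; the perfect classifier
#' sits in the top-left corner at (0, 100).
#'
#' @param reports A metrics-report tibble (see [metrics_report()]).
#' @return A ggplot object.
#' @export
plot_roc <- function(reports) {
  pts <- roc_points(reports)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fp_rate, y = .data$tp_rate,
                                    colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = palette_hex()) +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "FP rate (%)", y = "TP rate (%)", colour = "class") +
    ggplot2::theme_minimal()
}

#' @describeIn default_signatures Spectra plot with the three filter
#'   wavelengths marked.
#' @param object A `vineseg_signatures`.
#' @param ... Unused.
#' @method autoplot vineseg_signatures
#' @export
autoplot.vineseg_signatures <- function(object, ...) {
  ggplot2::ggplot(object$spectra,
                  ggplot2::aes(x = .data$wavelength, y = .data$mean,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(635, 660, 880), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance",
                  colour = "material") +
    ggplot2::theme_minimal()
}
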