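#' Plot a density map
#'
#' Raster view of the three class channels, faceted by class.
#'
#' @param object A `density_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~class_name) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "density")
}

#' Plot annotated or detected cell centers
#'
#' Cell centers colored by class, in image coordinates (origin top-left).
#'
#' @param object An [annotation_set()] or [detection_set()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.annotation_set <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$class_name)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse(limits = c(object$height - 1, 0)) +
    ggplot2::xlim(0, object$width - 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$image_id, colour = "class",
                  x = "x (px)", y = "y (px)")
}

#' Plot detections over the ground truth
#'
#' Truth centers as open circles, detections as crosses; a matched pair
#' shares a position up to the matching radius.
#'
#' @param pred A [detection_set()].
#' @param truth An [annotation_set()].
#' @return A ggplot.
#' @export
plot_detection_overlay <- function(pred, truth) {
  df <- bind_rows(
    as_tibble(truth) %>% mutate(kind = "truth"),
    as_tibble(pred) %>% mutate(kind = "prediction"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$class_name,
                                   shape = .data$kind)) +
    ggplot2::geom_point(size = 2, stroke = 1) +
    ggplot2::scale_shape_manual(values = c(truth = 1, prediction = 4)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "class", shape = NULL, x = "x (px)", y = "y (px)")
}

#' Plot a training loss history
#'
#' @param history Tibble with columns `epoch`, `loss` (from
#'   [train_network()]).
#' @return A ggplot with a log-scaled loss axis.
#' @export
plot_training_history <- function(history) {
  ggplot2::ggplot(history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "mean MSE loss")
}
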