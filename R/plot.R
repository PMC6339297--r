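#' Convert a 2D raster to a long tibble
#'
#' One row per pixel with 0-based coordinates `x`, `y` and `value` —
#' the form ggplot2 consumes.
#'
#' @param x A 2D raster ([micrograph()], [probability_map()],
#'   [label_map()], score map or plain matrix).
#' @return A tibble with columns `x`, `y`, `value`.
#' @export
raster_tbl <- function(x) {
  m <- raster_data(x)
  tibble::tibble(
    x = rep(0:(ncol(m) - 1), each = nrow(m)),
    y = rep(0:(nrow(m) - 1), times = ncol(m)),
    value = as.vector(m)
  )
}

raster_gg <- function(x, title) {
  ggplot2::ggplot(raster_tbl(x), ggplot2::aes(x = .data$x, y = .data$y,
                                              fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.micrograph <- function(object, ...) {
  raster_gg(object, attr(object, "name") %||% "micrograph")
}

#' @export
autoplot.probability_map <- function(object, ...) {
  raster_gg(object, "probability map")
}

#' @export
autoplot.label_map <- function(object, ...) {
  raster_gg(object, "label map")
}

#' Plot picks, optionally over their micrograph or map
#'
#' @param object A [pick_set()].
#' @param raster Optional 2D raster drawn underneath.
#' @param ... Unused.
#' @return A ggplot object; picks are open circles sized to the box and
#'   colored by score.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pick_set <- function(object, raster = NULL, ...) {
  p <- if (is.null(raster)) {
    ggplot2::ggplot() + ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() + ggplot2::theme_minimal()
  } else {
    raster_gg(raster, NULL)
  }
  p + ggplot2::geom_point(
    data = tibble::as_tibble(object),
    ggplot2::aes(x = .data$x, y = .data$y, color = .data$score),
    shape = 1, size = 3, stroke = 1
  ) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(title = sprintf("%d picks", nrow(object)))
}

#' Plot matched and unmatched picks
#'
#' @param object A `"pick_match"` from [match_picks()].
#' @param ... Unused.
#' @return A ggplot object with matched pairs joined by segments.
#' @export
autoplot.pick_match <- function(object, ...) {
  pr <- object$pairs
  ggplot2::ggplot(pr) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$pred_x, y = .data$pred_y,
                                       xend = .data$truth_x,
                                       yend = .data$truth_y),
                          color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(x = .data$truth_x, y = .data$truth_y),
                        color = "forestgreen", shape = 3) +
    ggplot2::geom_point(ggplot2::aes(x = .data$pred_x, y = .data$pred_y),
                        color = "steelblue", shape = 1) +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("TP %d / FP %d / FN %d", object$TP,
                                  object$FP, object$FN))
}
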