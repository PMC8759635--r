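#' Flow field as a tidy data frame
#'
#' One row per pixel with 0-based coordinates, the displacement components
#' and the magnitude — convenient for ggplot2 and dplyr summaries.
#'
#' @param field A [flow_field()].
#' @return Tibble with columns `row`, `col`, `u`, `v`, `magnitude`.
#' @export
flow_to_df <- function(field) {
  m <- flow_magnitude(field)
  tibble::tibble(row = as.vector(row(field$u)) - 1L,
                 col = as.vector(col(field$u)) - 1L,
                 u = as.vector(field$u), v = as.vector(field$v),
                 magnitude = as.vector(m))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a flow field
#'
#' Magnitude raster with displacement arrows on a subsampled grid.
#'
#' @param object A [flow_field()].
#' @param arrow_step Arrow grid spacing in pixels.
#' @param arrow_scale Multiplier applied to displacements for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_field <- function(object, arrow_step = 8L, arrow_scale = 3, ...) {
  df <- flow_to_df(object)
  sub <- df[df$row %% arrow_step == arrow_step %/% 2L &
            df$col %% arrow_step == arrow_step %/% 2L &
            df$magnitude > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::geom_segment(
      data = sub,
      ggplot2::aes(xend = .data$col + arrow_scale * .data$u,
                   yend = .data$row + arrow_scale * .data$v),
      arrow = ggplot2::arrow(length = ggplot2::unit(3, "pt")),
      colour = "white", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "|flow| (px/frame)") +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("Optical flow, frame pair t = %d",
                                  object$pair_index))
}

#' Plot a labeled segmentation mask
#'
#' @param object A [labeled_mask()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.labeled_mask <- function(object, ...) {
  lab <- object$labels
  df <- tibble::tibble(row = as.vector(row(lab)) - 1L,
                       col = as.vector(col(lab)) - 1L,
                       label = as.vector(lab))
  df$label <- factor(ifelse(df$label == 0L, NA, df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_discrete(na.value = "grey15", name = "region") +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("Segmented regions, frame t = %d",
                                  object$pair_index))
}

#' Overlay segmentation boundaries on an image frame
#'
#' @param frame An [image_frame()].
#' @param mask A [labeled_mask()] of the same dimensions.
#' @return A ggplot object.
#' @export
plot_segmentation <- function(frame, mask) {
  img <- tibble::tibble(row = as.vector(row(frame)) - 1L,
                        col = as.vector(col(frame)) - 1L,
                        intensity = as.vector(unclass(frame)))
  lab <- mask$labels
  edge <- lab > 0L & (
    .shift_matrix(lab, 1L, 0L, -1L) != lab |
    .shift_matrix(lab, -1L, 0L, -1L) != lab |
    .shift_matrix(lab, 0L, 1L, -1L) != lab |
    .shift_matrix(lab, 0L, -1L, -1L) != lab)
  ed <- tibble::tibble(row = row(lab)[edge] - 1L, col = col(lab)[edge] - 1L)
  ggplot2::ggplot(img, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = ed, colour = "red", size = 0.2) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("Frame t = %d with segmented perimeter",
                                  attr(frame, "index")))
}
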