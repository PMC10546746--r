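#' Plain white presentation theme for sequence graphics
#'
#' A minimal theme shared by all layers: white panel and plot background,
#' no grid lines, visible axis text and ticks, and the legend hidden by
#' default (letter fills are redundant with the glyphs themselves;
#' continuous-gradient plots re-enable it). Standard ggplot2 theme
#' composition applies, so later user overrides win and applying the
#' theme twice is a no-op.
#'
#' @param base_size Base font size in points.
#' @return A ggplot2 theme object.
#' @examples
#' ggplot2::ggplot() + theme_seq()
#' @export
theme_seq <- function(base_size = 11) {
  theme_minimal(base_size = base_size) +
    theme(
      panel.background = element_rect(fill = "white", colour = NA),
      plot.background = element_rect(fill = "white", colour = NA),
      panel.grid.major = element_blank(),
      panel.grid.minor = element_blank(),
      axis.ticks = element_line(colour = "grey30"),
      axis.text = element_text(colour = "grey30"),
      legend.position = "none",
      strip.text = element_text(face = "bold")
    )
}

#' Axis metadata of a layer
#'
#' The scale and label conventions a renderer should apply: integer x
#' breaks at every alignment position, a y label determined by the layer
#' (`"bits"`, `"probability"`, the bar statistic, or none), and for
#' alignment layers reversed y ticks at row centers labeled by sequence
#' index (sequence 1 on top).
#'
#' @param layer A layer or `seq_composition`.
#' @return A list with `x_breaks`, `xlab`, `ylab`, and (alignment only)
#'   `y_breaks`, `y_labels`, `reverse_y`.
#' @export
axis_metadata <- function(layer) UseMethod("axis_metadata")

#' @export
axis_metadata.seq_logo_layer <- function(layer) {
  list(x_breaks = layer$x_breaks, xlab = layer$xlab, ylab = layer$ylab)
}

#' @export
axis_metadata.seq_bar_layer <- function(layer) {
  list(x_breaks = layer$x_breaks, xlab = NULL, ylab = layer$ylab)
}

#' @export
axis_metadata.seq_align_layer <- function(layer) {
  k <- layer$n_rows
  list(x_breaks = layer$x_breaks, xlab = NULL, ylab = NULL,
       y_breaks = seq_len(k) - 0.5, y_labels = seq_len(k), reverse_y = TRUE)
}

#' @export
axis_metadata.seq_composition <- function(layer) {
  list(x_breaks = layer$x_breaks, xlab = NULL, ylab = NULL)
}
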