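#' Render a layer as a ggplot
#'
#' Turns a layer's drawing tables into a ggplot2 figure: grouped polygons
#' (with even-odd hole filling) for letter glyphs, tiles/rectangles for
#' alignment backgrounds and bar segments, [theme_seq()] and the layer's
#' axis metadata, and one facet panel per `seq_group` when the input was a
#' named mapping. The tables are used verbatim, so any edits made via
#' [mutate_layer()] or direct assignment show up in the figure.
#'
#' @param x A `seq_logo_layer`, `seq_align_layer`, `seq_bar_layer` or
#'   `seq_composition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' p <- seq_plot(logo_layer(c("ACGT", "ACGA"), method = "bits"))
#' @export
seq_plot <- function(x, ...) UseMethod("seq_plot")

glyph_geom <- function(data, continuous, gradient = NULL) {
  if (continuous) {
    list(
      geom_polygon(
        aes(x = .data$x, y = .data$y, group = .data$poly_id,
            subgroup = .data$piece, fill = .data$value),
        data = data, rule = "evenodd"),
      scale_fill_gradient(low = gradient[1],
                          high = gradient[length(gradient)]),
      theme(legend.position = "right")
    )
  } else {
    list(
      geom_polygon(
        aes(x = .data$x, y = .data$y, group = .data$poly_id,
            subgroup = .data$piece, fill = .data$col),
        data = data, rule = "evenodd"),
      scale_fill_identity()
    )
  }
}

facet_panels <- function(panels) {
  if (length(panels) > 1) {
    facet_wrap(~seq_group, scales = "free_x")
  }
}

#' @export
seq_plot.seq_logo_layer <- function(x, ...) {
  meta <- axis_metadata(x)
  ggplot() +
    glyph_geom(x$data, continuous = "value" %in% names(x$data),
               gradient = x$scheme$gradient) +
    facet_panels(x$panels) +
    scale_x_continuous(breaks = meta$x_breaks) +
    labs(x = meta$xlab, y = meta$ylab) +
    theme_seq()
}

#' @export
seq_plot.seq_align_layer <- function(x, ...) {
  meta <- axis_metadata(x)
  bg <- x$bg_data
  if (!"col" %in% names(bg)) {
    bg$col <- ifelse(bg$letter == "-", GAP_TILE_COLOR, "#F7F7F7")
  }
  p <- ggplot() +
    geom_tile(aes(x = .data$x, y = .data$y, width = .data$width,
                  height = .data$height, fill = .data$col),
              data = bg, colour = "white", linewidth = 0.2) +
    scale_fill_identity()
  if (!is.null(x$letter_data)) {
    d <- x$letter_data
    if ("value" %in% names(d)) {
      d$col <- values_to_hex(d$value, x$scheme$gradient)
    }
    p <- p + geom_polygon(
      aes(x = .data$x, y = .data$y, group = .data$poly_id,
          subgroup = .data$piece), fill = d$col,
      data = d, rule = "evenodd")
  }
  p +
    facet_panels(x$panels) +
    scale_x_continuous(breaks = meta$x_breaks) +
    scale_y_reverse(breaks = meta$y_breaks, labels = meta$y_labels) +
    labs(x = meta$xlab, y = meta$ylab) +
    theme_seq()
}

#' @export
seq_plot.seq_bar_layer <- function(x, ...) {
  meta <- axis_metadata(x)
  d <- x$bar_data
  continuous <- "value" %in% names(d)
  p <- ggplot()
  if (continuous) {
    p <- p + geom_rect(
      aes(xmin = .data$x - .data$width / 2, xmax = .data$x + .data$width / 2,
          ymin = .data$y_lo, ymax = .data$y_hi, fill = .data$value),
      data = d) +
      scale_fill_gradient(low = x$scheme$gradient[1],
                          high = x$scheme$gradient[length(x$scheme$gradient)])
  } else {
    p <- p + geom_rect(
      aes(xmin = .data$x - .data$width / 2, xmax = .data$x + .data$width / 2,
          ymin = .data$y_lo, ymax = .data$y_hi, fill = .data$col),
      data = d) +
      scale_fill_identity()
  }
  if (!is.null(x$letter_data)) {
    p <- p + geom_polygon(
      aes(x = .data$x, y = .data$y, group = .data$poly_id,
          subgroup = .data$piece),
      fill = x$letter_data$col, data = x$letter_data, rule = "evenodd")
  }
  p +
    facet_panels(x$panels) +
    scale_x_continuous(breaks = meta$x_breaks) +
    labs(x = meta$xlab, y = meta$ylab) +
    theme_seq() +
    if (continuous) theme(legend.position = "right") else NULL
}

#' @export
seq_plot.seq_composition <- function(x, ...) {
  p <- ggplot()
  if (!is.null(x$rects)) {
    p <- p + geom_rect(
      aes(xmin = .data$xmin, xmax = .data$xmax,
          ymin = .data$ymin, ymax = .data$ymax, fill = .data$fill),
      data = x$rects)
  }
  if (!is.null(x$polygons)) {
    p <- p + geom_polygon(
      aes(x = .data$x, y = .data$y, group = .data$poly_id,
          subgroup = .data$piece, fill = .data$fill),
      data = x$polygons, rule = "evenodd")
  }
  p +
    scale_fill_identity() +
    scale_x_continuous(breaks = x$x_breaks) +
    labs(x = NULL, y = NULL) +
    theme_seq()
}
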