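#' Build a per-position sequence-histogram layer
#'
#' Summarizes letter composition per alignment column as stacked bar
#' segments, ordered by the logo stacking rule (tallest segment on top).
#' `statistic = "count"` (default) stacks raw letter counts so a gap-free
#' column totals the number of sequences; `"proportion"` rescales every
#' nonzero column to total 1. Letter glyphs are drawn centered in each
#' segment unless suppressed (`show_letters = FALSE`, no-letter mode);
#' slivers shorter than 5% of their column total never get a glyph.
#'
#' `bar_data` is the public drawing table: one record per segment with
#' columns `letter`, `position`, `y_lo`, `y_hi`, `x`, `width`,
#' `seq_group`, `col` or `value`, and `group`.
#'
#' @inheritParams logo_layer
#' @param statistic `"count"` or `"proportion"`.
#' @param show_letters Draw glyphs inside segments? Default `TRUE`.
#' @return A `seq_bar_layer` with fields `bar_data`, `letter_data`,
#'   `statistic`, `font`, `scheme`, `x_breaks`, `ylab`, `panels`.
#' @examples
#' lay <- bar_layer(c("ACGT", "ACGA", "ACTA", "ACTA"))
#' lay$bar_data
#' @export
bar_layer <- function(input, statistic = c("count", "proportion"),
                      scheme = NULL, show_letters = TRUE,
                      font = default_font(), namespace = NULL) {
  statistic <- match.arg(statistic)
  panels <- normalize_input(input, namespace)
  scheme <- resolve_scheme(scheme, panel_letters(panels))
  font_data <- get_font(font)

  bars <- list(); letters <- list()
  for (p in panels) {
    pfm <- panel_pfm(p)
    hm <- if (statistic == "proportion") {
      to_probability(pfm)
    } else {
      height_matrix(unclass(pfm), "custom", p$label)
    }
    iv <- stack_heights(hm)
    tab <- tibble(letter = iv$letter, position = iv$position,
                  y_lo = iv$y_lo, y_hi = iv$y_hi,
                  x = iv$position, width = LETTER_WIDTH,
                  seq_group = p$label)
    tab <- cbind(tab, assign_colors(scheme, tab$letter))
    bars[[length(bars) + 1]] <- as_tibble(tab)

    if (show_letters) {
      totals <- tapply(iv$height, iv$position, sum)
      thresh <- 0.05 * totals[as.character(iv$position)]
      big <- iv[iv$height > thresh, , drop = FALSE]
      if (nrow(big)) {
        pad <- 0.1 * (big$y_hi - big$y_lo)   # 80% inset glyph per segment
        giv <- tibble(letter = big$letter, position = big$position,
                      y_lo = big$y_lo + pad, y_hi = big$y_hi - pad,
                      height = big$y_hi - big$y_lo - 2 * pad)
        gr <- glyph_rows(giv, p$label, font_data,
                         width = LETTER_WIDTH * 0.8)
        gr$interval <- NULL
        gr$col <- "#FFFFFF"
        gr$group <- gr$letter
        letters[[length(letters) + 1]] <- as_tibble(gr)
      }
    }
  }
  labels <- vapply(panels, `[[`, "", "label")
  bar_data <- set_panel_levels(as_tibble(do.call(rbind, bars)), labels)
  letter_data <- if (show_letters && length(letters)) {
    set_panel_levels(as_tibble(do.call(rbind, letters)), labels)
  }
  structure(
    list(bar_data = bar_data, letter_data = letter_data,
         statistic = statistic, font = font, scheme = scheme,
         x_breaks = seq_len(max(bar_data$position)),
         ylab = statistic, panels = labels),
    class = "seq_bar_layer"
  )
}

#' @export
print.seq_bar_layer <- function(x, ...) {
  cat("<seq_bar_layer> statistic '", x$statistic, "', ",
      nrow(x$bar_data), " segments, ", length(x$panels), " panel(s)\n",
      sep = "")
  invisible(x)
}

#' @export
mutate_layer.seq_bar_layer <- function(layer, letter = NULL, position = NULL,
                                       seq_group = NULL, col = NULL,
                                       value = NULL) {
  layer$bar_data <- edit_fill_table(layer$bar_data, letter, position,
                                    seq_group, col, value)
  layer
}

#' @export
layer_primitives.seq_bar_layer <- function(layer) {
  d <- layer$bar_data
  fill <- if ("col" %in% names(d)) d$col else {
    values_to_hex(d$value, layer$scheme$gradient)
  }
  rects <- tibble(xmin = d$x - d$width / 2, xmax = d$x + d$width / 2,
                  ymin = d$y_lo, ymax = d$y_hi, fill = fill)
  polys <- NULL
  if (!is.null(layer$letter_data)) {
    l <- layer$letter_data
    polys <- tibble(poly_id = l$poly_id, piece = l$piece, order = l$order,
                    x = l$x, y = l$y, fill = l$col)
  }
  list(polygons = polys, rects = rects)
}
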