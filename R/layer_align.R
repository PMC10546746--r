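#' Build a multiple-sequence-alignment layer
#'
#' Lays an alignment out as a grid of unit background tiles, one per
#' (sequence, position), with an optional letter-glyph overlay. The color
#' scheme paints either the tile backgrounds (`scheme_applied =
#' "BACKGROUND"`, letters drawn in a legible ink color) or the glyphs
#' themselves (`"LETTER"`, tiles left a neutral background). Gap (`-`)
#' cells get a pale neutral tile and no glyph.
#'
#' The background table `bg_data` is the public drawing table, one record
#' per tile with columns `letter`, `position`, `y_index` (sequence row,
#' first input sequence = 1, displayed as the top row), `x` (= position),
#' `y` (= y_index - 0.5), `width` (1), `height` (1), `seq_group` (panel),
#' and — in BACKGROUND mode only — `col` (hex fill) and `group` (fill
#' key). `letter_data` holds the glyph polygons, or is `NULL` when
#' `show_letters = FALSE` (no-letter mode).
#'
#' @param input Aligned sequences (character vector or [seq_set()]) or a
#'   named list of them (one facet panel per name).
#' @param scheme As in [logo_layer()].
#' @param scheme_applied `"BACKGROUND"` (default) or `"LETTER"`.
#' @param show_letters Draw letter glyphs? Default `TRUE`.
#' @param font A name from [list_fonts()].
#' @param namespace Optional alphabet override.
#' @return A `seq_align_layer` with fields `bg_data`, `letter_data`,
#'   `scheme_applied`, `font`, `scheme`, `x_breaks`, `n_rows`, `panels`.
#' @examples
#' lay <- align_layer(c("ACGT", "AC-T"))
#' lay$bg_data
#' @export
align_layer <- function(input, scheme = NULL,
                        scheme_applied = c("BACKGROUND", "LETTER"),
                        show_letters = TRUE, font = default_font(),
                        namespace = NULL) {
  scheme_applied <- match.arg(scheme_applied)
  panels <- normalize_input(input, namespace)
  if (any(vapply(panels, `[[`, "", "kind") != "seqs")) {
    stop("alignment input must be sequences, not a matrix", call. = FALSE)
  }
  scheme <- resolve_scheme(scheme, panel_letters(panels))
  font_data <- get_font(font)

  bg <- list(); letters <- list()
  for (p in panels) {
    ss <- p$value
    chmat <- seq_char_matrix(ss$sequences)
    k <- nrow(chmat); L <- ncol(chmat)
    tab <- tibble(
      letter = as.vector(chmat),
      position = rep(seq_len(L), each = k),
      y_index = rep(row_order(ss), times = L)
    )
    tab$x <- tab$position
    tab$y <- tab$y_index - 0.5
    tab$width <- 1
    tab$height <- 1
    tab$seq_group <- p$label
    if (scheme_applied == "BACKGROUND") {
      ac <- assign_colors(scheme, tab$letter)
      if ("value" %in% names(ac)) {
        ac$col <- values_to_hex(ac$value, scheme$gradient)
      }
      ac$col[tab$letter == "-"] <- GAP_TILE_COLOR
      tab$col <- ac$col
      tab$group <- ac$group
    }
    bg[[length(bg) + 1]] <- tab

    if (show_letters) {
      lt <- tab[tab$letter != "-", c("letter", "position", "y_index")]
      iv <- tibble(letter = lt$letter, position = lt$position,
                   y_lo = lt$y_index - 0.95, y_hi = lt$y_index - 0.05,
                   height = 0.9)
      gr <- glyph_rows(iv, p$label, font_data, width = LETTER_WIDTH)
      gr$y_index <- lt$y_index[gr$interval]
      gr$poly_id <- paste(gr$poly_id, gr$y_index, sep = "_")
      gr$interval <- NULL
      if (scheme_applied == "LETTER") {
        ac <- assign_colors(scheme, gr$letter)
        gr <- cbind(gr, ac)
      } else {
        tilecol <- tab$col[match(paste(gr$position, gr$y_index),
                                 paste(tab$position, tab$y_index))]
        gr$col <- ifelse(relative_luminance(tilecol) < 0.5,
                         "#FFFFFF", "#000000")
        gr$group <- gr$letter
      }
      letters[[length(letters) + 1]] <- as_tibble(gr)
    }
  }
  labels <- vapply(panels, `[[`, "", "label")
  bg <- set_panel_levels(as_tibble(do.call(rbind, bg)), labels)
  letter_data <- if (show_letters) {
    set_panel_levels(as_tibble(do.call(rbind, letters)), labels)
  }
  structure(
    list(bg_data = bg, letter_data = letter_data,
         scheme_applied = scheme_applied, font = font, scheme = scheme,
         x_breaks = seq_len(max(bg$position)),
         n_rows = max(bg$y_index), panels = labels),
    class = "seq_align_layer"
  )
}

#' Row indices of an alignment
#'
#' The y-axis assignment of the alignment layer: the first input sequence
#' gets `y_index = 1`, the second 2, and so on. The rendered y axis is
#' reversed, so sequence 1 reads as the top row.
#'
#' @param x A [seq_set()] or character vector of aligned sequences.
#' @return Integer vector `1:k` for `k` sequences.
#' @export
row_order <- function(x) {
  n <- if (inherits(x, "seq_set")) length(x$sequences) else length(x)
  seq_len(n)
}

#' @export
print.seq_align_layer <- function(x, ...) {
  cat("<seq_align_layer> ", x$n_rows, " sequences x ",
      max(x$bg_data$position), " positions, scheme on ",
      x$scheme_applied, if (is.null(x$letter_data)) ", no letters", "\n",
      sep = "")
  invisible(x)
}

#' @export
mutate_layer.seq_align_layer <- function(layer, letter = NULL,
                                         position = NULL, seq_group = NULL,
                                         col = NULL, value = NULL) {
  if (layer$scheme_applied == "BACKGROUND") {
    layer$bg_data <- edit_fill_table(layer$bg_data, letter, position,
                                     seq_group, col, value)
  } else {
    layer$letter_data <- edit_fill_table(layer$letter_data, letter,
                                         position, seq_group, col, value)
  }
  layer
}

#' @export
layer_primitives.seq_align_layer <- function(layer) {
  bg <- layer$bg_data
  fill <- if ("col" %in% names(bg)) bg$col else {
    ifelse(bg$letter == "-", GAP_TILE_COLOR, "#F7F7F7")
  }
  rects <- tibble(xmin = bg$x - bg$width / 2, xmax = bg$x + bg$width / 2,
                  ymin = bg$y - bg$height / 2, ymax = bg$y + bg$height / 2,
                  fill = fill)
  polys <- NULL
  if (!is.null(layer$letter_data)) {
    d <- layer$letter_data
    pf <- if ("col" %in% names(d)) d$col else {
      values_to_hex(d$value, layer$scheme$gradient)
    }
    polys <- tibble(poly_id = d$poly_id, piece = d$piece, order = d$order,
                    x = d$x, y = d$y, fill = pf)
  }
  list(polygons = polys, rects = rects)
}
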