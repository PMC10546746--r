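#' Build a sequence-logo layer
#'
#' Converts aligned sequences, a position frequency matrix, a custom
#' height matrix, or a named list of these (one facet panel per name) into
#' a sequence logo: per-position letter stacks whose heights encode
#' relative frequency (`method = "probability"`), information content in
#' bits (`method = "bits"`, the default), or arbitrary signed values
#' (`method = "custom"`, matrix input only; negative heights hang below
#' the axis).
#'
#' The returned object's `data` field is the public drawing table — a tidy
#' tibble with one row per glyph outline point and columns `letter`,
#' `position`, `piece` (outline sub-path; holes render even-odd), `order`,
#' `x`, `y`, `seq_group` (panel), `col` or `value` (scheme fill), `group`
#' (fill key) and `poly_id` (polygon identity). It can be inspected and
#' edited freely (see [mutate_layer()]); rendering via [seq_plot()] uses
#' the table verbatim.
#'
#' @param input Character vector of aligned sequences, a [seq_set()], a
#'   letters-by-positions matrix (counts for `probability`/`bits`, signed
#'   heights for `custom`), or a named list of these; names become facet
#'   panels in insertion order.
#' @param method `"bits"` (default), `"probability"`, or `"custom"`.
#' @param font A name from [list_fonts()].
#' @param scheme A scheme name from [list_schemes()], a
#'   [make_col_scheme()] object, or `NULL` to choose automatically from
#'   the alphabet (nucleotide scheme for nucleic alphabets, chemistry for
#'   amino acids, neutral grey otherwise).
#' @param namespace Optional alphabet for sequence input (defaults to
#'   detection).
#' @param correction Apply the small-sample correction in bits mode.
#' @return A `seq_logo_layer` with fields `data`, `method`, `font`,
#'   `scheme`, `xlab`, `ylab`, `x_breaks`, `panels`.
#' @examples
#' lay <- logo_layer(c("ACGT", "ACGA", "ACTA"), method = "bits")
#' head(lay$data)
#' @export
logo_layer <- function(input, method = c("bits", "probability", "custom"),
                       font = default_font(), scheme = NULL,
                       namespace = NULL, correction = FALSE) {
  method <- match.arg(method)
  panels <- normalize_input(input, namespace)
  if (method == "custom" && any(vapply(panels, `[[`, "", "kind") == "seqs")) {
    stop("input-type error: method = \"custom\" requires matrix input, ",
         "not sequences", call. = FALSE)
  }
  scheme <- resolve_scheme(scheme, panel_letters(panels))
  font_data <- get_font(font)

  tabs <- lapply(panels, function(p) {
    hm <- switch(method,
      custom = height_matrix(p$value, "custom", p$label),
      probability = to_probability(panel_pfm(p)),
      bits = to_bits(panel_pfm(p), correction = correction)
    )
    iv <- stack_heights(hm)
    gr <- glyph_rows(iv, p$label, font_data)
    gr$interval <- NULL
    gr
  })
  data <- do.call(rbind, tabs)
  data <- cbind(data, assign_colors(scheme, data$letter))
  labels <- vapply(panels, `[[`, "", "label")
  data <- set_panel_levels(as_tibble(data), labels)

  L <- max(c(1, data$position))
  structure(
    list(data = data, method = method, font = font, scheme = scheme,
         xlab = NULL,
         ylab = switch(method, bits = "bits", probability = "probability",
                       custom = NULL),
         x_breaks = seq_len(L), panels = labels),
    class = "seq_logo_layer"
  )
}

panel_pfm <- function(p) {
  if (p$kind == "seqs") build_pfm(p$value) else freq_matrix(p$value, p$label)
}

#' @export
print.seq_logo_layer <- function(x, ...) {
  cat("<seq_logo_layer> method '", x$method, "', ", length(x$panels),
      " panel(s), ", nrow(x$data), " drawing-table rows\n", sep = "")
  invisible(x)
}

#' Edit drawing-table records of a layer
#'
#' Record-level override of the fill of an existing layer: select records
#' by any combination of `letter`, `position` and `seq_group`, and set
#' their `col` (hex color) or `value`. This is how per-position coloring
#' is done — e.g. the same letter red at one position and grey at another.
#' Geometry columns are never touched.
#'
#' @param layer A `seq_logo_layer`, `seq_align_layer` or `seq_bar_layer`.
#' @param letter,position,seq_group Record selectors; `NULL` means "any".
#' @param col Replacement hex color (discrete fill).
#' @param value Replacement numeric value (continuous fill).
#' @return The layer with its drawing table edited.
#' @examples
#' lay <- logo_layer(c("ACGT", "ACGA"), method = "probability")
#' lay <- mutate_layer(lay, letter = "A", position = 1, col = "#FF0000")
#' @export
mutate_layer <- function(layer, letter = NULL, position = NULL,
                         seq_group = NULL, col = NULL, value = NULL) {
  UseMethod("mutate_layer")
}

edit_fill_table <- function(tab, letter, position, seq_group, col, value) {
  if (is.null(col) && is.null(value)) {
    return(tab)  # empty edit set: identity
  }
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(letter)) keep <- keep & tab$letter %in% letter
  if (!is.null(position)) keep <- keep & tab$position %in% position
  if (!is.null(seq_group)) keep <- keep & tab$seq_group %in% seq_group
  if (!any(keep)) {
    stop("edit error: no drawing-table record matches the selection",
         call. = FALSE)
  }
  if (!is.null(col)) {
    if (!"col" %in% names(tab)) {
      stop("edit error: this table has no `col` column (continuous scheme ",
           "or LETTER mode); edit `value` or the letter table instead",
           call. = FALSE)
    }
    tab$col[keep] <- col
  }
  if (!is.null(value)) {
    if (!"value" %in% names(tab)) {
      stop("edit error: this table has no `value` column", call. = FALSE)
    }
    tab$value[keep] <- value
  }
  tab
}

#' @export
mutate_layer.seq_logo_layer <- function(layer, letter = NULL, position = NULL,
                                        seq_group = NULL, col = NULL,
                                        value = NULL) {
  layer$data <- edit_fill_table(layer$data, letter, position, seq_group,
                                col, value)
  layer
}

#' Combine layers in one coordinate system
#'
#' Shifts each layer vertically by its offset and concatenates the drawing
#' tables into shared primitive tables (filled polygons and rectangles)
#' tagged by layer, so e.g. a logo can sit directly above the alignment it
#' summarizes. Inputs are not mutated. Continuous fills are resolved to
#' hex through their scheme gradient so all primitives share one identity
#' fill scale.
#'
#' @param layers A list of layers (`seq_logo_layer`, `seq_align_layer`,
#'   `seq_bar_layer`), optionally named for the layer tag.
#' @param offsets Numeric vector of per-layer y shifts (recycled if length
#'   1). Default 0.
#' @return A `seq_composition`: list with tibbles `polygons` (columns
#'   `layer`, `poly_id`, `piece`, `order`, `x`, `y`, `fill`) and `rects`
#'   (`layer`, `xmin`, `xmax`, `ymin`, `ymax`, `fill`), plus `x_breaks`.
#' @examples
#' logo <- logo_layer(c("ACGT", "ACGA"), method = "bits")
#' aln <- align_layer(c("ACGT", "ACGA"))
#' comp <- compose_layers(list(aln, logo), offsets = c(0, 2.5))
#' @export
compose_layers <- function(layers, offsets = 0) {
  stopifnot(is.list(layers), length(layers) > 0)
  offsets <- rep_len(offsets, length(layers))
  tags <- names(layers)
  if (is.null(tags)) tags <- rep("", length(layers))
  tags <- ifelse(nzchar(tags), tags, paste0("layer", seq_along(layers)))
  polys <- list(); rects <- list()
  for (i in seq_along(layers)) {
    prim <- layer_primitives(layers[[i]])
    if (!is.null(prim$polygons) && nrow(prim$polygons)) {
      p <- prim$polygons
      p$y <- p$y + offsets[i]
      p$layer <- tags[i]
      p$poly_id <- paste(tags[i], p$poly_id, sep = ".")
      polys[[length(polys) + 1]] <- p
    }
    if (!is.null(prim$rects) && nrow(prim$rects)) {
      r <- prim$rects
      r$ymin <- r$ymin + offsets[i]
      r$ymax <- r$ymax + offsets[i]
      r$layer <- tags[i]
      rects[[length(rects) + 1]] <- r
    }
  }
  polys <- if (length(polys)) do.call(rbind, polys) else NULL
  rects <- if (length(rects)) do.call(rbind, rects) else NULL
  xs <- unlist(lapply(layers, function(l) l$x_breaks))
  structure(list(polygons = polys, rects = rects,
                 x_breaks = sort(unique(xs))),
            class = "seq_composition")
}

# layer -> shared drawing primitives (identity-fill polygons and rects)
layer_primitives <- function(layer) UseMethod("layer_primitives")

#' @export
layer_primitives.seq_logo_layer <- function(layer) {
  d <- layer$data
  fill <- if ("col" %in% names(d)) d$col else {
    values_to_hex(d$value, layer$scheme$gradient)
  }
  list(polygons = tibble(poly_id = d$poly_id, piece = d$piece,
                         order = d$order, x = d$x, y = d$y, fill = fill),
       rects = NULL)
}
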