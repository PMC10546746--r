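#' List the built-in glyph fonts
#'
#' The package ships a catalog of 15 glyph-outline fonts, each covering
#' the printable ASCII characters (upper/lowercase letters, digits and
#' symbols) as normalized polygon outlines. The first name returned is the
#' default font used by all layers.
#'
#' @return Character vector of the 15 font names, stable across calls.
#' @examples
#' list_fonts()
#' @export
list_fonts <- function() {
  c("sans_bold", "sans", "sans_italic", "sans_bold_italic",
    "serif", "serif_bold", "serif_italic", "serif_bold_italic",
    "mono", "mono_bold", "mono_italic", "mono_bold_italic",
    "stix", "stix_bold", "stix_italic")
}

default_font <- function() list_fonts()[1]

#' Load the glyph outlines of a built-in font
#'
#' Each glyph is a set of polygon pieces (outer contours plus holes,
#' rendered with the even-odd fill rule) normalized to a tight unit
#' bounding box: `gx` and `gy` span exactly `[0, 1]` per character.
#'
#' @param name A font name from [list_fonts()].
#' @return A tibble of class `glyph_set` with columns `char`, `piece`,
#'   `order` (point order within piece), `gx`, `gy`, and attribute
#'   `font_name`. Faces are parsed once per session and cached.
#' @examples
#' head(get_font("sans_bold"))
#' @export
get_font <- function(name) {
  if (length(name) != 1 || !name %in% list_fonts()) {
    stop("unknown font '", paste(name, collapse = ","),
         "'; valid fonts are: ", paste(list_fonts(), collapse = ", "),
         call. = FALSE)
  }
  key <- paste0("font_", name)
  if (!is.null(.seqgrammar_cache[[key]])) return(.seqgrammar_cache[[key]])
  path <- system.file("extdata", "fonts", paste0(name, ".txt"),
                      package = "seqgrammar", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "# ")]  # "# " = metadata; "#\t" = the # glyph
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pts <- lapply(fields, function(f) {
    xy <- matrix(as.numeric(unlist(strsplit(strsplit(f[3], " ", fixed = TRUE)[[1]],
                                            ",", fixed = TRUE))),
                 ncol = 2, byrow = TRUE) / 1000
    tibble(char = f[1], piece = as.integer(f[2]),
           order = seq_len(nrow(xy)), gx = xy[, 1], gy = xy[, 2])
  })
  out <- do.call(rbind, pts)
  attr(out, "font_name") <- name
  class(out) <- c("glyph_set", class(out))
  .seqgrammar_cache[[key]] <- out
  out
}

#' Fetch one character's outline from a font
#'
#' @param font A font name or a `glyph_set` from [get_font()].
#' @param char A single character.
#' @return A `glyph_set` tibble restricted to `char` (possibly several
#'   pieces). Errors if the character has no outline in the font.
#' @export
get_glyph <- function(font, char) {
  gs <- if (inherits(font, "glyph_set")) font else get_font(font)
  out <- gs[gs$char == char, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("font '", attr(gs, "font_name"), "' has no outline for '",
         char, "'", call. = FALSE)
  }
  out
}

#' Place a glyph outline at a position and scale
#'
#' Affine placement of a unit glyph into a letter slot:
#' `x = x_center - width/2 + gx * width`. A positive `height` maps
#' `y = y_base + gy * height`; a negative `height` draws the glyph
#' *upright* in the interval `[y_base + height, y_base]` (it is shifted
#' below the base, not vertically mirrored), so letters below the axis of
#' a custom-height logo remain readable. `height = 0` yields a degenerate
#' zero-area polygon.
#'
#' @param outline A `glyph_set` tibble for a single character (see
#'   [get_glyph()]).
#' @param x_center Horizontal center of the letter slot.
#' @param width Slot width (> 0).
#' @param y_base Baseline y coordinate.
#' @param height Signed letter height.
#' @return A tibble with columns `letter`, `piece`, `order`, `x`, `y`.
#' @export
place_glyph <- function(outline, x_center, width, y_base, height) {
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  x <- x_center - width / 2 + outline$gx * width
  y <- if (height >= 0) {
    y_base + outline$gy * height
  } else {
    y_base + (1 - outline$gy) * height
  }
  tibble(letter = outline$char, piece = outline$piece,
         order = outline$order, x = x, y = y)
}
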