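# Shared input normalization and glyph-table helpers for the three layers.

LETTER_WIDTH <- 0.9  # letter/bar slot width as a fraction of one position

# Accepts a character vector, seq_set, matrix (counts or heights), or a
# named list mixing these (one panel per key, insertion order preserved).
# Returns a list of panels: each list(kind = "seqs"|"matrix", value = ...,
# label = chr).
normalize_input <- function(input, namespace = NULL) {
  panelize <- function(x, label) {
    if (inherits(x, "seq_set")) {
      x$panel_label <- label
      list(kind = "seqs", value = x, label = label)
    } else if (is.character(x)) {
      list(kind = "seqs", value = seq_set(x, namespace, label), label = label)
    } else if (is.matrix(x)) {
      if (is.null(rownames(x))) {
        stop("matrix input must have letter rownames", call. = FALSE)
      }
      list(kind = "matrix", value = x, label = label)
    } else {
      stop("unsupported input of class ", paste(class(x), collapse = "/"),
           call. = FALSE)
    }
  }
  if (is.null(input) || (is.list(input) && !inherits(input, "seq_set") &&
                         length(input) == 0) || length(input) == 0) {
    stop("empty input", call. = FALSE)
  }
  if (is.list(input) && !inherits(input, "seq_set") && !is.matrix(input)) {
    labs <- names(input)
    if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs)) {
      stop("mapping input must have unique non-empty names", call. = FALSE)
    }
    mapply(panelize, input, labs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  } else {
    list(panelize(input, "1"))
  }
}

panel_letters <- function(panels) {
  unique(unlist(lapply(panels, function(p) {
    if (p$kind == "seqs") p$value$alphabet else rownames(p$value)
  })))
}

# Stacked intervals -> placed glyph polygons, one row per outline point.
# Negative intervals (y_hi <= 0) are drawn upright below the baseline.
glyph_rows <- function(intervals, seq_group, font_data,
                       width = LETTER_WIDTH, x_center = NULL) {
  if (nrow(intervals) == 0) {
    return(tibble(letter = character(), position = integer(),
                  piece = integer(), order = integer(),
                  x = numeric(), y = numeric(), seq_group = character(),
                  poly_id = character(), interval = integer()))
  }
  xc <- if (is.null(x_center)) intervals$position else x_center
  out <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    g <- get_glyph(font_data, intervals$letter[i])
    placed <- if (intervals$height[i] >= 0) {
      place_glyph(g, xc[i], width, intervals$y_lo[i],
                  intervals$y_hi[i] - intervals$y_lo[i])
    } else {
      place_glyph(g, xc[i], width, intervals$y_hi[i],
                  intervals$y_lo[i] - intervals$y_hi[i])
    }
    placed$position <- intervals$position[i]
    placed$seq_group <- seq_group
    placed$poly_id <- paste(seq_group, intervals$position[i],
                            intervals$letter[i],
                            if (intervals$height[i] < 0) "neg" else "pos",
                            sep = "_")
    placed$interval <- i
    out[[i]] <- placed
  }
  res <- do.call(rbind, out)
  res[, c("letter", "position", "piece", "order", "x", "y",
          "seq_group", "poly_id", "interval")]
}

# seq_group columns become factors levelled in panel insertion order so
# facet_wrap() lays panels out in key order
set_panel_levels <- function(tab, labels) {
  tab$seq_group <- factor(tab$seq_group, levels = labels)
  tab
}

# map continuous scheme values to hex via the scheme gradient (used when a
# legend-free identity fill is needed, e.g. in compositions)
values_to_hex <- function(values, gradient) {
  rng <- range(values, na.rm = TRUE)
  span <- if (diff(rng) > 0) diff(rng) else 1
  ramp <- grDevices::colorRamp(gradient)
  out <- rep(FALLBACK_COLOR, length(values))
  ok <- is.finite(values)
  rgb <- ramp((values[ok] - rng[1]) / span)
  out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  out
}

# perceived luminance in [0,1] of #RRGGBB; used to pick legible letter ink
relative_luminance <- function(hex) {
  rgb <- col2rgb(hex) / 255
  as.numeric(0.2126 * rgb[1, ] + 0.7152 * rgb[2, ] + 0.0722 * rgb[3, ])
}
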