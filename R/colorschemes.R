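FALLBACK_COLOR <- "#808080"   # neutral grey for letters a scheme does not map
GAP_TILE_COLOR <- "#F0F0F0"   # pale neutral for gap tiles (distinct from fallback)
DEFAULT_GRADIENT <- c("#255C99", "#D62839")

#' List the built-in color schemes
#'
#' Eight named schemes: `nucleotide`, `nucleotide2` and `base_pairing` are
#' defined over the nucleic-acid alphabets; `chemistry`, `chemistry2`,
#' `hydrophobicity`, `clustalx` and `taylor` over the amino-acid alphabet.
#' All are discrete letter-to-color maps except `hydrophobicity`, which is
#' a continuous letter-to-value map (Kyte-Doolittle scale) rendered
#' through a gradient.
#'
#' @return Character vector of the 8 scheme names, stable across calls.
#' @examples
#' list_schemes()
#' @export
list_schemes <- function() {
  c("chemistry", "chemistry2", "hydrophobicity", "nucleotide",
    "nucleotide2", "base_pairing", "clustalx", "taylor")
}

scheme_registry <- function() {
  if (is.null(.seqgrammar_cache$palettes)) {
    path <- system.file("extdata", "color_schemes.tsv",
                        package = "seqgrammar", mustWork = TRUE)
    .seqgrammar_cache$palettes <- read.delim(path, colClasses = "character")
  }
  .seqgrammar_cache$palettes
}

#' Fetch a built-in color scheme
#'
#' @param name A scheme name from [list_schemes()].
#' @param alphabet Optional alphabet to restrict/extend the scheme to:
#'   letters the scheme does not map are assigned the neutral fallback
#'   color (`#808080`) for discrete schemes, `NA` for continuous ones.
#' @return A `col_scheme` object: a list with `name`, `kind` (`"discrete"`
#'   or `"continuous"`), `mapping` (named colors or named numeric values),
#'   `gradient` (continuous only) and `applies_to`.
#' @examples
#' get_col_scheme("nucleotide", alphabet_dna())
#' @export
get_col_scheme <- function(name, alphabet = NULL) {
  if (length(name) != 1 || !name %in% list_schemes()) {
    stop("unknown color scheme '", paste(name, collapse = ","),
         "'; valid schemes are: ", paste(list_schemes(), collapse = ", "),
         call. = FALSE)
  }
  reg <- scheme_registry()
  rows <- reg[reg$scheme == name, , drop = FALSE]
  kind <- rows$kind[1]
  if (kind == "discrete") {
    mapping <- setNames(rows$color, rows$letter)
  } else {
    mapping <- setNames(as.numeric(rows$value), rows$letter)
  }
  sch <- new_col_scheme(name, kind, mapping,
                        gradient = if (kind == "continuous") DEFAULT_GRADIENT)
  if (!is.null(alphabet)) sch <- restrict_scheme(sch, alphabet)
  sch
}

new_col_scheme <- function(name, kind, mapping, gradient = NULL) {
  if (kind == "discrete") {
    bad <- !grepl("^#[0-9A-Fa-f]{6}$", mapping)
    if (any(bad)) {
      stop("invalid hex color(s): ", paste(mapping[bad], collapse = ", "),
           call. = FALSE)
    }
  } else {
    if (any(!is.finite(mapping))) {
      stop("continuous scheme values must be finite", call. = FALSE)
    }
    if (length(gradient) < 2) {
      stop("continuous scheme needs a gradient with >= 2 stops",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, kind = kind, mapping = mapping, gradient = gradient,
         applies_to = names(mapping)),
    class = "col_scheme"
  )
}

restrict_scheme <- function(scheme, alphabet) {
  alphabet <- as.character(alphabet)
  if (scheme$kind == "discrete") {
    mapping <- setNames(
      ifelse(alphabet %in% names(scheme$mapping),
             scheme$mapping[alphabet], FALLBACK_COLOR),
      alphabet)
  } else {
    mapping <- setNames(scheme$mapping[alphabet], alphabet)
  }
  scheme$mapping <- mapping
  scheme$applies_to <- alphabet
  scheme
}

#' @export
print.col_scheme <- function(x, ...) {
  cat("<col_scheme> '", x$name, "' (", x$kind, "), ",
      length(x$mapping), " letters\n", sep = "")
  invisible(x)
}

#' Build a custom color scheme
#'
#' Supply exactly one of `colors` (a discrete letter-to-hex map) or
#' `values` (a continuous letter-to-number map rendered through a
#' two-stop gradient by default).
#'
#' @param letters Character vector of letters.
#' @param colors Hex colors (`#RRGGBB`), same length as `letters`.
#' @param values Finite numeric values, same length as `letters`.
#' @param name Scheme name; default `"custom"`.
#' @param gradient Gradient stops for continuous schemes (>= 2 colors).
#' @return A `col_scheme`.
#' @examples
#' make_col_scheme(c("A", "C"), colors = c("#FF0000", "#0000FF"))
#' make_col_scheme(c("A", "C"), values = c(0, 1))
#' @export
make_col_scheme <- function(letters, colors = NULL, values = NULL,
                            name = "custom", gradient = DEFAULT_GRADIENT) {
  if (length(letters) == 0) {
    stop("`letters` must be non-empty", call. = FALSE)
  }
  if (is.null(colors) == is.null(values)) {
    stop("supply exactly one of `colors` or `values`", call. = FALSE)
  }
  if (!is.null(colors)) {
    if (length(colors) != length(letters)) {
      stop("`colors` must match `letters` in length", call. = FALSE)
    }
    new_col_scheme(name, "discrete", setNames(as.character(colors), letters))
  } else {
    if (length(values) != length(letters)) {
      stop("`values` must match `letters` in length", call. = FALSE)
    }
    new_col_scheme(name, "continuous", setNames(as.numeric(values), letters),
                   gradient = gradient)
  }
}

#' Assign scheme colors (or values) to a letter column
#'
#' The record-level operation every layer uses: for a discrete scheme it
#' yields a hex `col` column (scheme color, or the neutral fallback for
#' unmapped letters); for a continuous scheme a numeric `value` column to
#' be passed through the scheme's gradient by the renderer. A `group`
#' column (the letter) is added so fill aesthetics resolve per letter.
#'
#' @param scheme A `col_scheme`.
#' @param table_letters Character vector of letters, one per record.
#' @return A tibble with `group` plus `col` (discrete) or `value`
#'   (continuous), `nrow = length(table_letters)`.
#' @export
assign_colors <- function(scheme, table_letters) {
  stopifnot(inherits(scheme, "col_scheme"))
  table_letters <- as.character(table_letters)
  if (scheme$kind == "discrete") {
    col <- unname(scheme$mapping[table_letters])
    col[is.na(col)] <- FALLBACK_COLOR
    tibble(col = col, group = table_letters)
  } else {
    tibble(value = unname(scheme$mapping[table_letters]),
           group = table_letters)
  }
}

# default scheme by alphabet: nucleic -> nucleotide, amino -> chemistry,
# anything else -> all-fallback grey
auto_scheme <- function(letters) {
  letters <- setdiff(unique(as.character(letters)), "-")
  if (all(letters %in% c(alphabet_dna(), "U"))) {
    get_col_scheme("nucleotide")
  } else if (all(letters %in% alphabet_aa())) {
    get_col_scheme("chemistry")
  } else {
    new_col_scheme("none", "discrete",
                   setNames(rep(FALLBACK_COLOR, length(letters)), letters))
  }
}

resolve_scheme <- function(scheme, letters) {
  if (is.null(scheme)) {
    auto_scheme(letters)
  } else if (inherits(scheme, "col_scheme")) {
    scheme
  } else {
    get_col_scheme(scheme)
  }
}
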