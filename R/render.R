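#' Render a layer to an image file
#'
#' Builds the ggplot for a layer (or composition) via [seq_plot()] and
#' writes it to PNG, SVG or PDF, chosen by the output file extension.
#' The drawing tables are deterministic for fixed inputs; pixel output is
#' backend-dependent.
#'
#' @param x A layer, composition, or ggplot object.
#' @param out Output path ending in `.png`, `.svg` or `.pdf`.
#' @param width,height Figure size in inches.
#' @param dpi Resolution for PNG output.
#' @return `out`, invisibly.
#' @export
render_figure <- function(x, out, width = 7, height = 3.5, dpi = 150) {
  plot <- if (inherits(x, "ggplot")) x else seq_plot(x)
  ext <- tolower(tools::file_ext(out))
  dev <- switch(ext,
    png = grDevices::png,
    svg = grDevices::svg,
    pdf = grDevices::pdf,
    stop("unsupported output format '.", ext,
         "'; use .png, .svg or .pdf", call. = FALSE)
  )
  ggsave(out, plot = plot, device = dev, width = width, height = height,
         dpi = dpi)
  invisible(out)
}

#' Write a layer's main drawing table as TSV
#'
#' The byte-level contract used for reproducibility checks: the same
#' inputs (and seed, where simulation is involved) always produce an
#' identical table file.
#'
#' @param x A layer or composition.
#' @param out Output TSV path.
#' @return `out`, invisibly.
#' @export
write_layer_table <- function(x, out) {
  tab <- main_table(x)
  tab <- as.data.frame(lapply(tab, function(col) {
    if (is.numeric(col)) formatC(col, format = "g", digits = 15) else
      as.character(col)
  }), stringsAsFactors = FALSE)
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

main_table <- function(x) {
  if (inherits(x, "seq_logo_layer")) x$data
  else if (inherits(x, "seq_align_layer")) x$bg_data
  else if (inherits(x, "seq_bar_layer")) x$bar_data
  else if (inherits(x, "seq_composition")) {
    if (!is.null(x$polygons)) x$polygons else x$rects
  } else stop("no drawing table for class ",
              paste(class(x), collapse = "/"), call. = FALSE)
}
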