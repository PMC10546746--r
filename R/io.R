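#' Read sequences from a FASTA file
#'
#' Records are returned in file order. The alphabet is auto-detected from
#' the residues ([detect_alphabet()]) unless overridden. Equal-length
#' validation happens here, so the result is ready for any layer.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Optional alphabet override.
#' @param panel_label Panel label of the returned [seq_set()].
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, alphabet = NULL, panel_label = "1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("FASTA parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  seq_set(as.character(set), alphabet, panel_label)
}

#' Write sequences to a FASTA file
#'
#' @param x A [seq_set()] or character vector.
#' @param path Output path.
#' @param names Record names; defaults to `seq1..seqN`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, names = NULL) {
  seqs <- if (inherits(x, "seq_set")) x$sequences else x
  if (is.null(names)) names <- paste0("seq", seq_along(seqs))
  set <- Biostrings::BStringSet(setNames(seqs, names))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a position frequency matrix
#'
#' Two plain-text dialects are supported. `"jaspar"`: an optional `>`
#' header line followed by rows like `A [ 3 1 0 ]`; `"plain"`: a
#' whitespace-separated grid whose first column is the letter label.
#' `"auto"` (default) picks jaspar when a bracket or `>` header is seen.
#' Fractional counts are allowed; negative ones are rejected.
#'
#' @param path Path to the matrix file.
#' @param dialect `"auto"`, `"jaspar"` or `"plain"`.
#' @param panel_label Panel label.
#' @return A [freq_matrix()] with letters in file order.
#' @export
read_pfm <- function(path, dialect = c("auto", "jaspar", "plain"),
                     panel_label = "1") {
  counts <- parse_matrix_file(path, match.arg(dialect))
  freq_matrix(counts, panel_label)
}

# shared row parser for PFM and signed height-matrix files
parse_matrix_file <- function(path, dialect = c("auto", "jaspar", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (dialect == "auto") {
    dialect <- if (any(startsWith(lines, ">")) || any(grepl("\\[", lines))) {
      "jaspar"
    } else {
      "plain"
    }
  }
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) == 0) stop("no matrix rows in ", path, call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    ln <- lines[i]
    if (dialect == "jaspar") ln <- gsub("\\[|\\]", " ", ln)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) {
      stop("parse error: row ", i, " of ", path, " has no counts",
           call. = FALSE)
    }
    counts <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(counts))) {
      stop("parse error: non-numeric count in row ", i, " ('", lines[i],
           "')", call. = FALSE)
    }
    list(letter = parts[1], counts = counts)
  })
  lens <- vapply(rows, function(r) length(r$counts), 1L)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop("parse error: ragged matrix, row ", bad, " has ", lens[bad],
         " counts but row 1 has ", lens[1], call. = FALSE)
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- vapply(rows, `[[`, "", "letter")
  counts
}
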