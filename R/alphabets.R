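#' Built-in alphabets
#'
#' Character vectors of the standard residue alphabets, in alphabetical
#' order. Alphabets are case-sensitive: the built-ins are uppercase, and a
#' lowercase (or mixed) alphabet can be supplied anywhere a `namespace` /
#' `alphabet` argument is accepted.
#'
#' @return A character vector of single characters.
#' @examples
#' alphabet_dna()
#' alphabet_aa()
#' @export
alphabet_dna <- function() c("A", "C", "G", "T")

#' @rdname alphabet_dna
#' @export
alphabet_rna <- function() c("A", "C", "G", "U")

#' @rdname alphabet_dna
#' @export
alphabet_aa <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Detect the alphabet of a set of sequences
#'
#' Census rule: any of the amino-acid-only characters `E F I L P Q Z`
#' implies the amino-acid alphabet; otherwise a `U` implies RNA; otherwise
#' DNA. If the detected standard alphabet does not cover every non-gap
#' character (custom letters, digits, symbols, lowercase), the sorted set
#' of distinct non-gap characters is used as a custom alphabet instead.
#'
#' @param sequences Character vector of sequences.
#' @return Character vector of single characters (the alphabet).
#' @examples
#' detect_alphabet(c("ACGT"))
#' detect_alphabet(c("ACGU"))
#' detect_alphabet(c("PEPTIDE"))
#' @export
detect_alphabet <- function(sequences) {
  chars <- unique(unlist(strsplit(sequences, "", fixed = TRUE)))
  chars <- setdiff(chars, "-")
  guess <- if (any(chars %in% c("E", "F", "I", "L", "P", "Q", "Z"))) {
    alphabet_aa()
  } else if ("U" %in% chars) {
    alphabet_rna()
  } else {
    alphabet_dna()
  }
  if (all(chars %in% guess)) guess else sort(chars)
}
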