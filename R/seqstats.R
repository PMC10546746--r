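#' Construct a validated set of aligned sequences
#'
#' A `seq_set` is the basic sequence container: equal-length aligned
#' sequences over a declared alphabet (the "namespace"), optionally tagged
#' with a panel label used for faceting. The gap character `-` is always
#' permitted and never counts as a residue.
#'
#' @param sequences Character vector of aligned sequences (equal length,
#'   length >= 1 each).
#' @param alphabet Character vector of permitted single characters. Default
#'   `NULL` auto-detects via [detect_alphabet()]. Comparisons are
#'   case-sensitive.
#' @param panel_label Panel (facet) label; default `"1"`.
#' @return An object of class `seq_set`: a list with elements `sequences`,
#'   `alphabet`, `panel_label`.
#' @examples
#' seq_set(c("ACGT", "ACGA"))
#' @export
seq_set <- function(sequences, alphabet = NULL, panel_label = "1") {
  if (length(sequences) == 0 || !is.character(sequences)) {
    stop("`sequences` must be a non-empty character vector", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (any(lens < 1)) stop("sequences must have length >= 1", call. = FALSE)
  if (length(unique(lens)) != 1) {
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(alphabet)) alphabet <- detect_alphabet(sequences)
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0) stop("alphabet must be non-empty", call. = FALSE)
  if (anyDuplicated(alphabet)) {
    stop("alphabet contains duplicate characters", call. = FALSE)
  }
  if (any(nchar(alphabet) != 1)) {
    stop("alphabet members must be single characters", call. = FALSE)
  }
  chmat <- seq_char_matrix(sequences)
  bad <- !(chmat %in% c(alphabet, "-"))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(chmat)), arr.ind = TRUE)[1, ]
    stop("alphabet error: character '", chmat[idx[1], idx[2]],
         "' at position ", idx[2], " of sequence ", idx[1],
         " is not in the alphabet", call. = FALSE)
  }
  structure(
    list(sequences = unname(sequences), alphabet = alphabet,
         panel_label = as.character(panel_label)),
    class = "seq_set"
  )
}

#' @export
print.seq_set <- function(x, ...) {
  cat("<seq_set> ", length(x$sequences), " sequences x ",
      nchar(x$sequences[1]), " positions, alphabet {",
      paste(x$alphabet, collapse = ""), "}, panel '", x$panel_label, "'\n",
      sep = "")
  invisible(x)
}

# sequences -> n x L character matrix
seq_char_matrix <- function(sequences) {
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}

#' Construct a position frequency matrix
#'
#' @param counts Numeric matrix, letters (rownames) x positions. All counts
#'   must be nonnegative and at least one column must have a positive sum.
#' @param panel_label Panel label carried through to layers.
#' @return A `freq_matrix`: a numeric matrix with class and `panel_label`
#'   attributes.
#' @export
freq_matrix <- function(counts, panel_label = "1") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique letter rownames", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("validation error: counts must be finite and nonnegative",
         call. = FALSE)
  }
  if (all(colSums(counts) == 0)) {
    stop("at least one column must have a positive sum", call. = FALSE)
  }
  colnames(counts) <- seq_len(ncol(counts))
  structure(counts, class = c("freq_matrix", class(matrix())),
            panel_label = as.character(panel_label))
}

#' Tally a position frequency matrix from aligned sequences
#'
#' Counts how often each alphabet letter occurs at each alignment column.
#' Gap characters (`-`) contribute to no letter's count, so a gap-only
#' column is all zero (and is later rendered empty rather than erroring).
#' Letter rows are exactly the alphabet, in alphabet order.
#'
#' @param x A [seq_set()], or a character vector of aligned sequences.
#' @param alphabet Optional alphabet override when `x` is a character
#'   vector.
#' @param panel_label Panel label when `x` is a character vector.
#' @return A [freq_matrix()] with one row per alphabet letter.
#' @examples
#' build_pfm(c("AC", "AG"))
#' @export
build_pfm <- function(x, alphabet = NULL, panel_label = "1") {
  if (!inherits(x, "seq_set")) x <- seq_set(x, alphabet, panel_label)
  chmat <- seq_char_matrix(x$sequences)
  counts <- vapply(
    seq_len(ncol(chmat)),
    function(j) {
      tab <- table(factor(chmat[, j], levels = x$alphabet))
      as.numeric(tab)
    },
    numeric(length(x$alphabet))
  )
  counts <- matrix(counts, nrow = length(x$alphabet),
                   dimnames = list(x$alphabet, seq_len(ncol(chmat))))
  structure(counts, class = c("freq_matrix", class(matrix())),
            panel_label = x$panel_label)
}

#' Convert counts to per-position probabilities
#'
#' Each column is divided by its sum; a zero-sum column (all gaps) yields a
#' zero probability column, which downstream layers render as an empty
#' position.
#'
#' @param pfm A [freq_matrix()] (a plain letters-by-positions matrix is
#'   accepted and validated).
#' @return A `height_matrix` with `mode = "probability"`; every nonzero
#'   column sums to 1.
#' @examples
#' to_probability(build_pfm(c("AC", "AG", "AG", "AT")))
#' @export
to_probability <- function(pfm) {
  pfm <- as_freq_matrix(pfm)
  cs <- colSums(pfm)
  p <- sweep(unclass(pfm), 2, ifelse(cs > 0, cs, 1), "/")
  height_matrix(p, mode = "probability",
                panel_label = attr(pfm, "panel_label"))
}

#' Convert counts to information-content letter heights (bits)
#'
#' For each column with letter probabilities `p` over an alphabet of size
#' `s`, the Shannon entropy is `H = -sum(p * log2(p))` (with `0 log 0 = 0`)
#' and the information content is `IC = log2(s) - H`. Each letter's height
#' is `p * IC`, so the stack height at a position equals its information
#' content: 0 bits for a uniform column, `log2(s)` bits for a fully
#' conserved one. With `correction = TRUE` the small-sample entropy bias
#' term `e_n = (s - 1) / (2 * ln(2) * n)` is subtracted (clamped at zero),
#' where `n` is the column's count total.
#'
#' @inheritParams to_probability
#' @param correction Apply the small-sample correction? Default `FALSE`.
#' @return A `height_matrix` with `mode = "bits"`.
#' @examples
#' to_bits(build_pfm(c("ACGT", "ACGT")))
#' @export
to_bits <- function(pfm, correction = FALSE) {
  pfm <- as_freq_matrix(pfm)
  s <- nrow(pfm)
  cs <- colSums(pfm)
  p <- sweep(unclass(pfm), 2, ifelse(cs > 0, cs, 1), "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  H <- -colSums(plogp)
  ic <- log2(s) - H
  if (correction) ic <- ic - (s - 1) / (2 * log(2) * ifelse(cs > 0, cs, 1))
  ic <- pmax(ic, 0)
  ic[cs == 0] <- 0
  h <- sweep(p, 2, ic, "*")
  height_matrix(h, mode = "bits", panel_label = attr(pfm, "panel_label"))
}

as_freq_matrix <- function(x, panel_label = "1") {
  if (inherits(x, "freq_matrix")) return(x)
  freq_matrix(x, panel_label)
}

#' Construct a letter-height matrix
#'
#' The common currency of all logo modes: signed per-(letter, position)
#' heights. Mode invariants are enforced: probability heights lie in
#' `[0, 1]` with nonzero columns summing to 1; bits heights are nonnegative
#' with column sums at most `log2(nrow)`; custom heights are unrestricted
#' in sign.
#'
#' @param heights Numeric matrix, letters (rownames) x positions.
#' @param mode One of `"probability"`, `"bits"`, `"custom"`.
#' @param panel_label Panel label.
#' @return A `height_matrix` (classed numeric matrix with `mode` and
#'   `panel_label` attributes).
#' @export
height_matrix <- function(heights, mode = c("custom", "probability", "bits"),
                          panel_label = "1") {
  mode <- match.arg(mode)
  heights <- as.matrix(heights)
  if (is.null(rownames(heights)) || anyDuplicated(rownames(heights))) {
    stop("heights must have unique letter rownames", call. = FALSE)
  }
  if (any(!is.finite(heights))) {
    stop("heights must be finite", call. = FALSE)
  }
  tol <- 1e-9
  cs <- colSums(heights)
  if (mode == "probability") {
    if (any(heights < -tol) || any(heights > 1 + tol)) {
      stop("probability heights must lie in [0, 1]", call. = FALSE)
    }
    nz <- cs > tol
    if (any(abs(cs[nz] - 1) > tol)) {
      stop("nonzero probability columns must sum to 1", call. = FALSE)
    }
  } else if (mode == "bits") {
    if (any(heights < -tol)) {
      stop("bits heights must be nonnegative", call. = FALSE)
    }
    if (any(cs > log2(nrow(heights)) + tol)) {
      stop("bits column sums cannot exceed log2(number of letters)",
           call. = FALSE)
    }
  }
  colnames(heights) <- seq_len(ncol(heights))
  structure(heights, class = c("height_matrix", class(matrix())),
            mode = mode, panel_label = as.character(panel_label))
}

#' Stack letter heights into drawing intervals
#'
#' Implements the logo stacking rule. At each position, letters with
#' positive height tile `[0, sum of positive heights]` bottom-to-top by
#' increasing height, so the tallest letter sits on top; letters with
#' negative height tile `[-sum(|negative|), 0]` top-to-bottom by increasing
#' magnitude, so the most negative letter ends lowest. Ties are broken by
#' alphabet (row) order, the earlier letter nearer the baseline on both
#' sides. Zero-height letters emit no interval.
#'
#' @param hm A `height_matrix` (or plain letters-by-positions matrix,
#'   treated as custom heights).
#' @return A tibble with columns `letter`, `position`, `y_lo`, `y_hi`,
#'   `height` (`height = y_hi - y_lo` for positive letters, negative of it
#'   for negative letters).
#' @examples
#' stack_heights(to_probability(build_pfm(c("AC", "AG", "AG", "AT"))))
#' @export
stack_heights <- function(hm) {
  if (!inherits(hm, "height_matrix")) hm <- height_matrix(hm)
  letters_ <- rownames(hm)
  out <- vector("list", ncol(hm))
  for (j in seq_len(ncol(hm))) {
    h <- unname(unclass(hm)[, j])
    pos <- which(h > 0)
    neg <- which(h < 0)
    rows <- list()
    if (length(pos)) {
      ord <- pos[order(h[pos], pos)]        # increasing height, earlier letter lower
      hi <- cumsum(h[ord])
      lo <- c(0, hi[-length(hi)])
      rows$pos <- tibble(letter = letters_[ord], position = j,
                         y_lo = lo, y_hi = hi, height = h[ord])
    }
    if (length(neg)) {
      ord <- neg[order(abs(h[neg]), neg)]   # increasing |height|, nearest zero first
      lo <- -cumsum(abs(h[ord]))
      hi <- c(0, lo[-length(lo)])
      rows$neg <- tibble(letter = letters_[ord], position = j,
                         y_lo = lo, y_hi = hi, height = h[ord])
    }
    out[[j]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- tibble(letter = character(), position = integer(),
                  y_lo = numeric(), y_hi = numeric(), height = numeric())
  }
  as_tibble(res)
}

#' Extract a window from full-length sequences
#'
#' Returns the 1-based inclusive substring window `[start, start + width - 1]`
#' of each sequence, preserving input order. Useful for cutting aligned
#' fragments (e.g. a motif window) out of full-length sequences.
#'
#' @param sequences Character vector.
#' @param start 1-based start position (>= 1).
#' @param width Window width (>= 1).
#' @return Character vector of the extracted windows.
#' @examples
#' extract_seqs("ABCDEF", start = 2, width = 3)
#' @export
extract_seqs <- function(sequences, start, width) {
  if (length(start) != 1 || start < 1 || start != round(start)) {
    stop("`start` must be a single integer >= 1", call. = FALSE)
  }
  if (length(width) != 1 || width < 1 || width != round(width)) {
    stop("`width` must be a single integer >= 1", call. = FALSE)
  }
  end <- start + width - 1
  short <- which(nchar(sequences) < end)
  if (length(short)) {
    stop("range error: window [", start, ", ", end,
         "] exceeds sequence ", short[1], " (length ",
         nchar(sequences[short[1]]), ")", call. = FALSE)
  }
  substr(sequences, start, end)
}

#' Simulate aligned sequences around a consensus
#'
#' Generates `n` sequences of the consensus length. Each position equals
#' the consensus letter with probability `1 - mutation_rate`, otherwise a
#' uniformly chosen *other* alphabet letter. Deterministic for a fixed
#' seed; the caller's random stream is left untouched.
#'
#' @param consensus Consensus string over `alphabet`.
#' @param n Number of sequences.
#' @param mutation_rate Per-position substitution probability in `[0, 1]`.
#' @param alphabet Alphabet; default detects from the consensus.
#' @param seed Integer random seed (required, for reproducible fixtures).
#' @param panel_label Panel label of the returned [seq_set()].
#' @return A [seq_set()] of `n` simulated sequences.
#' @examples
#' simulate_sequences("TGACTCA", n = 5, mutation_rate = 0.1, seed = 1)
#' @export
simulate_sequences <- function(consensus, n, mutation_rate,
                               alphabet = NULL, seed, panel_label = "1") {
  if (length(consensus) != 1 || !nzchar(consensus)) {
    stop("`consensus` must be a single non-empty string", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("`mutation_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(alphabet)) alphabet <- detect_alphabet(consensus)
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0) stop("alphabet must be non-empty", call. = FALSE)
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (!all(cons %in% alphabet)) {
    stop("consensus contains characters outside the alphabet", call. = FALSE)
  }
  L <- length(cons)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  mat <- matrix(rep(cons, each = n), nrow = n)
  mut <- matrix(stats::runif(n * L) < mutation_rate, nrow = n)
  for (j in seq_len(L)) {
    k <- sum(mut[, j])
    if (k > 0) {
      others <- setdiff(alphabet, cons[j])
      if (length(others) > 0) {
        mat[mut[, j], j] <- sample(others, k, replace = TRUE)
      }
    }
  }
  seq_set(apply(mat, 1, paste, collapse = ""), alphabet, panel_label)
}
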