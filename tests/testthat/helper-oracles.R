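# Independent oracles used across tests. These deliberately re-derive
# quantities by a different route than the package internals.

# signed polygon area (shoelace formula)
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# brute-force stacking: sort by height (ties by row index), tile cumulative
# intervals; returns data.frame letter, y_lo, y_hi for one column
brute_stack_column <- function(h, letters) {
  pos <- which(h > 0)
  neg <- which(h < 0)
  out <- NULL
  if (length(pos)) {
    ord <- pos[order(h[pos], pos)]
    hi <- cumsum(h[ord]); lo <- c(0, hi[-length(hi)])
    out <- rbind(out, data.frame(letter = letters[ord], y_lo = lo, y_hi = hi))
  }
  if (length(neg)) {
    ord <- neg[order(abs(h[neg]), neg)]
    lo <- -cumsum(abs(h[ord])); hi <- c(0, lo[-length(lo)])
    out <- rbind(out, data.frame(letter = letters[ord], y_lo = lo, y_hi = hi))
  }
  out
}

# even-odd point-in-polygon over a set of pieces (ray casting, +x ray)
point_covered_evenodd <- function(px, py, pieces) {
  crossings <- 0L
  for (p in pieces) {
    x <- p$x; y <- p$y
    n <- length(x)
    j <- c(n, seq_len(n - 1))
    for (i in seq_len(n)) {
      x1 <- x[j[i]]; y1 <- y[j[i]]; x2 <- x[i]; y2 <- y[i]
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (xint > px) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

# random count matrix over a given alphabet
random_count_matrix <- function(letters, L, max_count = 20) {
  m <- matrix(sample(0:max_count, length(letters) * L, replace = TRUE),
              nrow = length(letters), dimnames = list(letters, NULL))
  if (all(colSums(m) == 0)) m[1, 1] <- 1
  m
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
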