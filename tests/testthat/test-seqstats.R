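test_that("build_pfm tallies letters per column, excluding gaps", {
  pfm <- build_pfm(c("AC", "AG"))
  expect_equal(rownames(pfm), c("A", "C", "G", "T"))
  expect_equal(unclass(pfm)[, 1], c(A = 2, C = 0, G = 0, T = 0))
  expect_equal(unclass(pfm)[, 2], c(A = 0, C = 1, G = 1, T = 0))

  gap <- build_pfm("A-", alphabet = alphabet_dna())
  expect_equal(sum(unclass(gap)[, 2]), 0)
})

test_that("build_pfm matches an independent per-column tally on simulated data", {
  ss <- simulate_sequences("ACGTACGTAC", n = 100, mutation_rate = 0.3,
                           seed = 42)
  pfm <- build_pfm(ss)
  chars <- do.call(rbind, strsplit(ss$sequences, ""))
  for (j in seq_len(ncol(chars))) {
    for (l in ss$alphabet) {
      expect_equal(unclass(pfm)[l, j], sum(chars[, j] == l))
    }
  }
})

test_that("sequence validation reports alignment and alphabet errors", {
  expect_error(build_pfm(c("AC", "ACG")), "alignment error")
  expect_error(build_pfm(c("AX"), alphabet = alphabet_dna()),
               "alphabet error.*'X'.*position 2")
  expect_error(seq_set(c("AC"), alphabet = c("A", "A", "C")), "duplicate")
})

test_that("to_probability normalizes nonzero columns and keeps zero columns empty", {
  pfm <- freq_matrix(matrix(c(2, 0, 0, 0,
                              3, 1, 0, 0), nrow = 4,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  p <- to_probability(pfm)
  expect_equal(unclass(p)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unclass(p)[, 2], c(A = 0.75, C = 0.25, G = 0, T = 0))
  expect_equal(attr(p, "mode"), "probability")

  gap <- to_probability(build_pfm("A-", alphabet = alphabet_dna()))
  expect_equal(unname(unclass(gap)[, 2]), rep(0, 4))
})

test_that("probability columns sum to one over random matrices", {
  set.seed(11)
  for (i in 1:50) {
    m <- random_count_matrix(alphabet_dna(), L = 8)
    p <- to_probability(freq_matrix(m))
    cs <- colSums(unclass(p))
    nz <- colSums(m) > 0
    expect_true(all(abs(cs[nz] - 1) < 1e-9))
    expect_true(all(cs[!nz] == 0))
  }
})

test_that("information content follows the entropy formula", {
  letters <- c("A", "C", "G", "T")
  uniform <- freq_matrix(matrix(c(5, 5, 5, 5), 4,
                                dimnames = list(letters, NULL)))
  expect_equal(max(abs(unclass(to_bits(uniform)))), 0)

  conserved <- build_pfm(c("A", "A", "A"))
  b <- to_bits(conserved)
  expect_equal(unclass(b)["A", 1], 2)
  expect_equal(sum(unclass(b)[, 1]), 2)

  skewed <- freq_matrix(matrix(c(3, 1, 0, 0), 4,
                               dimnames = list(letters, NULL)))
  p <- c(0.75, 0.25)
  H <- -sum(p * log2(p))               # independent entropy summation
  ic_oracle <- 2 - H
  b2 <- unclass(to_bits(skewed))[, 1]
  expect_equal(sum(b2), ic_oracle, tolerance = 1e-9)
  expect_equal(unname(b2["A"]), 0.75 * ic_oracle, tolerance = 1e-9)
  expect_equal(unname(b2["C"]), 0.25 * ic_oracle, tolerance = 1e-9)
  expect_equal(ic_oracle, 1.1887, tolerance = 1e-4)
})

test_that("small-sample correction subtracts (s-1)/(2 ln2 n), clamped at zero", {
  conserved <- build_pfm(c("A", "A", "A", "A"))
  b <- to_bits(conserved, correction = TRUE)
  e_n <- 3 / (2 * log(2) * 4)
  expect_equal(unclass(b)["A", 1], 2 - e_n, tolerance = 1e-12)

  # a single sequence: correction exceeds IC, clamps at 0
  single <- build_pfm("A")
  expect_equal(sum(unclass(to_bits(single, correction = TRUE))), 0)
})

test_that("bits column sums are bounded by log2(alphabet size)", {
  set.seed(7)
  for (i in 1:30) {
    m <- random_count_matrix(alphabet_aa(), L = 5)
    b <- to_bits(freq_matrix(m))
    cs <- colSums(unclass(b))
    expect_true(all(cs >= -1e-9 & cs <= log2(20) + 1e-9))
  }
})

test_that("stacking orders letters shortest-bottom, tallest-top", {
  hm <- height_matrix(matrix(c(0.5, 0.3, 0.2, 0), 4,
                             dimnames = list(c("A", "C", "G", "T"), NULL)),
                      "probability")
  iv <- stack_heights(hm)
  expect_equal(iv$letter, c("G", "C", "A"))
  expect_equal(iv$y_lo, c(0, 0.2, 0.5))
  expect_equal(iv$y_hi, c(0.2, 0.5, 1.0), tolerance = 1e-12)
})

test_that("negative heights stack below zero, most negative lowest", {
  hm <- height_matrix(matrix(c(1, -0.5, -0.2, 0), 4,
                             dimnames = list(c("A", "C", "G", "T"), NULL)))
  iv <- stack_heights(hm)
  expect_equal(iv[iv$letter == "A", ]$y_lo, 0)
  expect_equal(iv[iv$letter == "A", ]$y_hi, 1)
  expect_equal(iv[iv$letter == "G", ]$y_lo, -0.2)  # nearest zero
  expect_equal(iv[iv$letter == "G", ]$y_hi, 0)
  expect_equal(iv[iv$letter == "C", ]$y_lo, -0.7)  # most negative lowest
  expect_equal(iv[iv$letter == "C", ]$y_hi, -0.2)
})

test_that("stacking matches the brute-force sort oracle on random columns", {
  set.seed(3)
  letters <- alphabet_dna()
  for (i in 1:200) {
    h <- round(stats::runif(4, -1, 2), 3)
    hm <- height_matrix(matrix(h, 4, dimnames = list(letters, NULL)))
    iv <- stack_heights(hm)
    oracle <- brute_stack_column(h, letters)
    expect_equal(iv$letter, oracle$letter)
    expect_equal(iv$y_lo, oracle$y_lo, tolerance = 1e-12)
    expect_equal(iv$y_hi, oracle$y_hi, tolerance = 1e-12)
    # partition of [0, sum positive]: no gaps/overlaps, argmax on top
    posiv <- iv[iv$y_lo >= 0, ]
    if (nrow(posiv)) {
      expect_equal(max(posiv$y_hi), sum(h[h > 0]), tolerance = 1e-12)
      expect_equal(posiv$y_lo, c(0, head(posiv$y_hi, -1)), tolerance = 1e-12)
      # argmax letter on top; among tied maxima the later letter sits higher
      expect_equal(posiv$letter[nrow(posiv)],
                   letters[max(which(h == max(h)))])
    }
  }
})

test_that("extract_seqs windows 1-based inclusive and errors out of range", {
  expect_equal(extract_seqs("ABCDEF", 2, 3), "BCD")
  expect_equal(extract_seqs("AB", 1, 2), "AB")
  s <- c("ACGTACGT", "TTTTACGT")
  expect_equal(extract_seqs(s, 1, nchar(s[1])), s)  # identity window
  set.seed(9)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    str <- paste(sample(LETTERS, n, replace = TRUE), collapse = "")
    st <- sample(seq_len(n), 1)
    w <- sample(seq_len(n - st + 1), 1)
    expect_equal(nchar(extract_seqs(str, st, w)), w)
  }
  expect_error(extract_seqs(c("ABCDEF", "AB"), 2, 3), "range error.*sequence 2")
})

test_that("simulate_sequences honors mutation rate extremes and the seed", {
  all_same <- simulate_sequences("ACGT", n = 10, mutation_rate = 0,
                                 seed = 1)
  expect_true(all(all_same$sequences == "ACGT"))

  flipped <- simulate_sequences("AAAA", n = 10, mutation_rate = 1,
                                alphabet = c("A", "B"), seed = 1)
  expect_true(all(flipped$sequences == "BBBB"))

  a <- simulate_sequences("ACGT", 20, 0.5, seed = 5)
  b <- simulate_sequences("ACGT", 20, 0.5, seed = 5)
  expect_identical(a$sequences, b$sequences)
})

test_that("simulated consensus frequency is within 3 binomial SE of 1 - rate", {
  n <- 2000; rate <- 0.2
  ss <- simulate_sequences("TGACTCA", n = n, mutation_rate = rate, seed = 77)
  chars <- do.call(rbind, strsplit(ss$sequences, ""))
  cons <- strsplit("TGACTCA", "")[[1]]
  se <- sqrt(rate * (1 - rate) / n)
  for (j in seq_along(cons)) {
    freq <- mean(chars[, j] == cons[j])
    expect_lt(abs(freq - (1 - rate)), 3 * se)
  }
})

test_that("pfm of zero-rate simulation has consensus argmax with count n", {
  ss <- simulate_sequences("CACGTG", n = 25, mutation_rate = 0, seed = 2)
  pfm <- unclass(build_pfm(ss))
  cons <- strsplit("CACGTG", "")[[1]]
  for (j in seq_along(cons)) {
    expect_equal(rownames(pfm)[which.max(pfm[, j])], cons[j])
    expect_equal(max(pfm[, j]), 25)
  }
})

test_that("simulate_sequences leaves the caller's random stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_sequences("ACGT", 5, 0.5, seed = 99))
  expect_identical(.Random.seed, before)
})
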