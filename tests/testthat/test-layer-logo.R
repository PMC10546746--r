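test_that("a fully conserved column spans 2 bits; probability tops stay <= 1", {
  lay <- logo_layer(c("A", "A", "A"), namespace = alphabet_dna(),
                    method = "bits")
  expect_equal(range(lay$data$y), c(0, 2), tolerance = 1e-9)
  expect_equal(unique(lay$data$letter), "A")
  expect_equal(lay$ylab, "bits")

  prob <- logo_layer(c("ACGT", "ACGA", "TGCA"), method = "probability")
  expect_lte(max(prob$data$y), 1 + 1e-9)
  expect_equal(prob$ylab, "probability")
})

test_that("letter x-extents stay inside the position slot", {
  lay <- logo_layer(c("ACGT", "ACGA", "TGCA"), method = "bits")
  for (pos in unique(lay$data$position)) {
    xs <- lay$data$x[lay$data$position == pos]
    expect_gt(min(xs), pos - 0.5)
    expect_lt(max(xs), pos + 0.5)
  }
})

test_that("polygon stack heights reproduce the height-matrix column sums", {
  seqs <- c("ACGT", "ACGA", "TGCA", "ACGT")
  for (method in c("probability", "bits")) {
    lay <- logo_layer(seqs, method = method)
    hm <- if (method == "probability") {
      to_probability(build_pfm(seqs))
    } else {
      to_bits(build_pfm(seqs))
    }
    for (pos in seq_len(4)) {
      top <- max(lay$data$y[lay$data$position == pos])
      expect_equal(top, sum(unclass(hm)[, pos]), tolerance = 1e-9)
    }
  }
})

test_that("custom heights draw on both sides of zero and round-trip exactly", {
  m <- matrix(c(1, -0.5), nrow = 2, dimnames = list(c("A", "C"), NULL))
  lay <- logo_layer(m, method = "custom")
  a <- lay$data[lay$data$letter == "A", ]
  c_ <- lay$data[lay$data$letter == "C", ]
  expect_equal(range(a$y), c(0, 1), tolerance = 1e-9)
  expect_equal(range(c_$y), c(-0.5, 0), tolerance = 1e-9)
  expect_null(lay$ylab)

  set.seed(14)
  letters_ <- c("A", "C", "G", "T")
  m2 <- matrix(round(stats::runif(20, -2, 2), 4), nrow = 4,
               dimnames = list(letters_, NULL))
  m2[abs(m2) < 0.05] <- 0.5   # avoid degenerate slivers
  lay2 <- logo_layer(m2, method = "custom")
  for (pos in seq_len(ncol(m2))) {
    for (l in letters_) {
      rows <- lay2$data[lay2$data$position == pos & lay2$data$letter == l, ]
      sgn <- if (min(rows$y) < -1e-12) -1 else 1
      expect_equal(sgn * diff(range(rows$y)), unname(m2[l, pos]), tolerance = 1e-9)
    }
  }
})

test_that("custom method rejects sequence input; empty input rejected", {
  expect_error(logo_layer(c("ACGT"), method = "custom"), "input-type error")
  expect_error(logo_layer(character()), "empty input")
  expect_error(logo_layer(list()), "empty input")
})

test_that("mapping input produces one panel per key in insertion order", {
  inp <- list(second = c("ACGT", "ACGA"), first = c("TTTT", "TTTA"),
              third = c("GGGG", "GGGA"))
  lay <- logo_layer(inp, method = "bits")
  expect_equal(levels(lay$data$seq_group), c("second", "first", "third"))
  expect_equal(length(unique(lay$data$seq_group)), 3)
  flat <- logo_layer(c("ACGT", "ACGA"))
  expect_equal(unique(as.character(flat$data$seq_group)), "1")
})

test_that("mutate_layer recolors selected records and nothing else", {
  seqs <- c("RACGTFR", "RACGTFR", "RACGTFR")
  lay <- logo_layer(seqs, namespace = alphabet_aa(), method = "probability")
  edited <- mutate_layer(lay, letter = "R", position = 1, col = "#FF0000")
  edited <- mutate_layer(edited, letter = "R", position = 7, col = "#808080")
  expect_true(all(edited$data$col[edited$data$letter == "R" &
                                  edited$data$position == 1] == "#FF0000"))
  expect_true(all(edited$data$col[edited$data$letter == "R" &
                                  edited$data$position == 7] == "#808080"))
  geom_cols <- c("letter", "position", "piece", "order", "x", "y")
  expect_identical(edited$data[geom_cols], lay$data[geom_cols])
  untouched <- edited$data$position %in% c(2:6)
  expect_identical(edited$data$col[untouched], lay$data$col[untouched])

  expect_identical(mutate_layer(lay)$data, lay$data)   # empty edit set
  expect_error(mutate_layer(lay, letter = "Z", position = 1, col = "#000000"),
               "edit error")
})

test_that("compose_layers shifts, tags and never mutates its inputs", {
  seqs <- c("ACGT", "ACGA")
  logo <- logo_layer(seqs, method = "bits")
  aln <- align_layer(seqs)
  before <- aln$bg_data

  solo <- compose_layers(list(logo), offsets = 0)
  prim <- seqgrammar:::layer_primitives(logo)$polygons
  expect_equal(solo$polygons$y, prim$y)
  expect_equal(solo$polygons$x, prim$x)

  comp <- compose_layers(list(aln = aln, logo = logo),
                         offsets = c(0, length(seqs) + 0.5))
  expect_identical(aln$bg_data, before)
  aln_y <- c(comp$rects$ymin, comp$rects$ymax,
             comp$polygons$y[comp$polygons$layer == "aln"])
  logo_y <- comp$polygons$y[comp$polygons$layer == "logo"]
  expect_lt(max(aln_y), min(logo_y) + 1e-9)

  swapped <- compose_layers(list(logo = logo, aln = aln),
                            offsets = c(length(seqs) + 0.5, 0))
  ord <- function(d) d[order(d$poly_id, d$order), ]
  expect_equal(ord(swapped$polygons), ord(comp$polygons))
})
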