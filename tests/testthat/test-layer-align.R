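test_that("a single 'T' yields the canonical background-tile record", {
  lay <- align_layer("T")
  bg <- lay$bg_data
  expect_equal(nrow(bg), 1)
  expect_equal(bg$letter, "T")
  expect_equal(bg$position, 1)
  expect_equal(bg$y_index, 1)
  expect_equal(bg$x, 1)
  expect_equal(bg$y, 0.5)
  expect_equal(bg$width, 1)
  expect_equal(bg$height, 1)
  expect_equal(as.character(bg$seq_group), "1")
  expect_equal(bg$col, "#D62839")
  expect_equal(bg$group, "T")
})

test_that("the tile grid is the exact Cartesian product of rows and positions", {
  seqs <- c("ACGTA", "AC-TA", "TTGCA")
  lay <- align_layer(seqs)
  bg <- lay$bg_data
  expect_equal(nrow(bg), 15)
  expect_equal(nrow(unique(bg[c("position", "y_index")])), 15)
  expect_setequal(bg$y_index, 1:3)
  expect_setequal(bg$position, 1:5)
  # tiles partition [0.5, L + 0.5] x [0, k]
  expect_equal(range(bg$x - bg$width / 2, bg$x + bg$width / 2), c(0.5, 5.5))
  expect_equal(range(bg$y - bg$height / 2, bg$y + bg$height / 2), c(0, 3))
})

test_that("y_index counts from the first sequence and y = y_index - 0.5", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(1:6, 1); L <- sample(1:8, 1)
    seqs <- vapply(seq_len(k), function(z) {
      paste(sample(alphabet_dna(), L, replace = TRUE), collapse = "")
    }, "")
    lay <- align_layer(seqs, show_letters = FALSE)
    expect_setequal(lay$bg_data$y_index, seq_len(k))
    expect_equal(lay$bg_data$y, lay$bg_data$y_index - 0.5)
    expect_equal(lay$bg_data$letter[lay$bg_data$y_index == 1],
                 strsplit(seqs[1], "")[[1]])
  }
  expect_equal(row_order(seq_set(c("AC", "GT", "AA"))), 1:3)
  meta <- axis_metadata(align_layer(c("AC", "GT")))
  expect_true(meta$reverse_y)   # first sequence displayed as top row
})

test_that("BACKGROUND mode colors tiles; LETTER mode colors glyphs instead", {
  seqs <- c("ACGT", "AC-T")
  bgm <- align_layer(seqs, scheme_applied = "BACKGROUND")
  expect_true(all(c("col", "group") %in% names(bgm$bg_data)))
  sch <- get_col_scheme("nucleotide")
  non_gap <- bgm$bg_data$letter != "-"
  expect_true(all(bgm$bg_data$col[non_gap] %in%
                    c(sch$mapping, "#808080")))
  # BACKGROUND-mode glyphs use legible ink, not scheme colors
  expect_true(all(bgm$letter_data$col %in% c("#000000", "#FFFFFF")))

  ltm <- align_layer(seqs, scheme_applied = "LETTER")
  expect_false(any(c("col", "group") %in% names(ltm$bg_data)))
  expect_true(all(ltm$letter_data$col %in% c(sch$mapping, "#808080")))
})

test_that("gap cells get the pale neutral tile and no glyph", {
  lay <- align_layer(c("A-G", "AAG"))
  gap <- lay$bg_data[lay$bg_data$letter == "-", ]
  expect_equal(gap$col, "#F0F0F0")
  expect_false(any(lay$letter_data$position == 2 &
                     lay$letter_data$y_index == 1))
})

test_that("letter polygons stay inside their tiles", {
  lay <- align_layer(c("ACGT", "TGCA"))
  d <- lay$letter_data
  expect_true(all(d$x > d$position - 0.5 & d$x < d$position + 0.5))
  expect_true(all(d$y >= d$y_index - 1 & d$y <= d$y_index))
})

test_that("no-letter mode omits the letter table entirely", {
  lay <- align_layer(c("ACGT", "TGCA"), show_letters = FALSE)
  expect_null(lay$letter_data)
  expect_equal(nrow(lay$bg_data), 8)
})

test_that("alignment facets follow mapping keys in insertion order", {
  lay <- align_layer(list(b = c("ACGT"), a = c("TTTT", "TTAA")))
  expect_equal(levels(lay$bg_data$seq_group), c("b", "a"))
  expect_equal(sum(lay$bg_data$seq_group == "b"), 4)
  expect_equal(sum(lay$bg_data$seq_group == "a"), 8)
})

test_that("matrix input is rejected for alignments", {
  m <- matrix(1:4, 2, dimnames = list(c("A", "C"), NULL))
  expect_error(align_layer(m), "sequences")
})
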