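# seqgrammar

Grammar-of-graphics visualization of per-position sequence composition
in R: **sequence logos** (probability, information-bits and
custom-height modes), **multiple-sequence-alignment tile diagrams**, and
**per-position stacked histograms**, built as composable ggplot2 layers.

seqgrammar is for anyone who works with aligned nucleic-acid or
amino-acid sequences — transcription-factor binding motifs, splice
sites, kinase substrate windows, alignments of homologs — and wants
publication-quality, fully scriptable figures whose every mark can be
inspected and edited as data. The distinguishing design decision is that
**each layer exposes its drawing table publicly**: a tidy tibble of
letter polygons, background tiles or bar segments that you can read,
filter, and mutate record by record before rendering. Per-position
recoloring, layer surgery, and stacking several layers in one coordinate
system are all ordinary data manipulation, not package internals.

## The statistics at the core

For $n$ aligned sequences over an alphabet of $s$ letters, the position
frequency matrix counts $c_{\ell j}$, occurrences of letter $\ell$ at
column $j$ (gaps `-` count toward nothing). Letter heights are then:

* **probability**: $p_{\ell j} = c_{\ell j} / \sum_k c_{kj}$ — columns
  sum to 1;
* **bits**: with entropy $H_j = -\sum_\ell p_{\ell j}\log_2 p_{\ell j}$,
  the information content is $IC_j = \log_2 s - H_j$ and letter heights
  are $p_{\ell j}\,IC_j$ — a conserved DNA column spans 2 bits, a
  uniform one 0. An optional small-sample correction subtracts
  $e_n = (s-1)/(2\ln 2\, n_j)$, clamped at zero;
* **custom**: any signed letters-by-positions matrix; negative heights
  hang below the axis.

Letters stack shortest-at-bottom, tallest-on-top (negative heights
mirror this below zero), and are drawn as polygon glyphs from a bundled
catalog of 15 fonts, colored by one of 8 built-in color schemes (or a
custom discrete/continuous scheme).

## Worked example

```r
library(seqgrammar)

# 20 synthetic AP-1-like sites around the consensus TGACTCA
seqs <- simulate_sequences("TGACTCA", n = 20, mutation_rate = 0.15,
                           seed = 42)
pfm <- build_pfm(seqs)
unclass(pfm)
#>    1  2  3  4  5  6  7
#> A  2  2 18  1  3  0 19
#> C  0  1  0 16  0 18  1
#> G  0 16  1  2  0  0  0
#> T 18  1  1  1 17  2  0

round(colSums(unclass(to_bits(pfm))), 3)
#>     1     2     3     4     5     6     7
#> 1.531 0.978 1.431 0.978 1.390 1.531 1.714
```

Column 1 contains 18 T and 2 A out of 20, so its information content is
$2 - H = 1.531$ bits — highly but not perfectly conserved; the most
degenerate columns (2 and 4) carry under 1 bit. The logo draws exactly
these numbers:

```r
lay <- logo_layer(seqs, method = "bits")
lay
#> <seq_logo_layer> method 'bits', 1 panel(s), 286 drawing-table rows
head(lay$data, 3)
#> # A tibble: 3 × 10
#>   letter position piece order     x      y seq_group poly_id   col     group
#> 1 A             1     1     1 1.17  0.0279 1         1_1_A_pos #109648 A
#> 2 A             1     1     2 0.827 0.0279 1         1_1_A_pos #109648 A
#> 3 A             1     1     3 0.772 0      1         1_1_A_pos #109648 A

seq_plot(lay)                                  # a ggplot; + works as usual
render_figure(lay, "ap1_logo.png")             # or .svg / .pdf

# recolor one record set, then stack the logo above its alignment
lay2 <- mutate_layer(lay, letter = "T", position = 1, col = "#FF00FF")
comp <- compose_layers(list(aln = align_layer(seqs), logo = lay2),
                       offsets = c(0, 20.5))
seq_plot(comp)
```

The alignment layer's background table follows a fixed schema — for the
single sequence `"T"`:

```r
align_layer("T")$bg_data
#>   letter position y_index x   y width height seq_group     col group
#> 1      T        1       1 1 0.5     1      1         1 #D62839     T
```

A command-line interface wraps the same functions
(`inst/cli/seqgrammar`): subcommands `logo`, `align`, `bar`, `fonts`,
`schemes`, `simulate`, with `--table-out` exposing the drawing table as
TSV. See `?cli`.

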