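---
title: "seqgrammar: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqgrammar: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 2.5)
library(seqgrammar)
```

seqgrammar draws the three standard pictures of per-position sequence
composition — sequence logos, multiple-sequence-alignment tile diagrams,
and stacked per-position histograms — as ggplot2 layers whose drawing
data are ordinary tidy tables. This vignette explains the statistics
behind the layers, the geometric conventions, the choices we made where
convention does not fully pin things down, and what the bundled
synthetic data can and cannot tell you about real data.

## From sequences to letter heights

Everything starts from a **position frequency matrix** (PFM): given $n$
aligned sequences of length $L$ over an alphabet of $s$ letters,
`build_pfm()` tallies $c_{\ell j}$, the number of sequences carrying
letter $\ell$ at column $j$. The gap character `-` is not a residue: it
contributes to no letter's count, so a gap-only column is all zero and is
rendered as an empty position rather than an error. Matching the
display side, alphabets are case-sensitive ('a' and 'A' are distinct
letters, so lowercase logos are possible), and any set of distinct
single characters — digits, punctuation — can serve as the alphabet.

Letter heights come in three modes:

* **probability** — $p_{\ell j} = c_{\ell j} / \sum_k c_{k j}$; every
  nonzero column sums to exactly 1.
* **bits** — the information-content logo. With column entropy
  $H_j = -\sum_\ell p_{\ell j} \log_2 p_{\ell j}$ (taking
  $0 \log 0 = 0$), the column's information content is
  $IC_j = \log_2 s - H_j$ and each letter's height is
  $p_{\ell j} \cdot IC_j$. A uniform column carries 0 bits; a fully
  conserved DNA column carries $\log_2 4 = 2$ bits, all of it on the
  conserved letter.
* **custom** — the caller supplies the letters-by-positions height
  matrix directly; values may be negative, which is how depletion or
  signed scores are usually drawn.

The small-sample entropy bias correction
$e_n = (s - 1) / (2 \ln 2 \cdot n_j)$ (with $n_j$ the column's count
total) can be subtracted from $IC_j$ via `to_bits(correction = TRUE)`,
clamped at zero. It is **off by default**: the uncorrected definition is
the dominant convention in logo tools, and it preserves the exact
"conserved column = $\log_2 s$ bits" identity that users expect to read
off the axis. Analyses of very small alignments (tens of sequences or
fewer) should consider turning it on.

## The stacking rule

At each position, letters with positive height tile
$[0, \sum h^+]$ bottom-to-top in order of increasing height: the tallest
letter always ends on top, the shortest at the bottom. Negative heights
tile $[-\sum |h^-|, 0]$ top-to-bottom by increasing magnitude, so the
most negative letter ends lowest — the two sides are mirror images of
the same rule. Ties are broken by alphabet order with the earlier letter
nearer the baseline; the point of fixing a tie-break at all is
determinism, so that identical inputs give byte-identical drawing
tables (which the test suite and the CLI's `--table-out` verify
literally, by hashing the serialized tables).

## Glyph geometry

Letters are drawn as filled polygons, not text, so every rendering
backend produces the same shapes and the drawing table fully describes
the figure. The package ships a catalog of 15 faces (sans, serif, mono
and stix families in regular/bold/italic variants), each covering the
printable ASCII range. Outlines were flattened from openly licensed
font files (DejaVu and STIX families) at a fixed chord tolerance of
1.5% of the em and quantized to a 0..1000 integer grid — both recorded
in each catalog file's header so the catalog can be regenerated
reproducibly (`scripts/build_font_catalog.py`). Sub-paths are kept as
separate *pieces* and filled with the even-odd rule, which is what
preserves the holes in O, B, 8 and friends; the renderer maps pieces to
ggplot2's polygon `subgroup` aesthetic.

Each glyph is normalized to a **tight** unit box: after normalization
its coordinates span exactly $[0,1]$ in both axes, so a stacked letter
exactly fills its interval. This is the standard logo-rendering
convention; the price, worth stating, is that relative letter
proportions are distorted (a period fills its slot just like a W).

Placement is affine: a letter in the slot of position $x$ with interval
$[y_{lo}, y_{hi}]$ occupies
$x \pm 0.45$ horizontally (letters take 0.9 of the unit slot, leaving a
visible gutter) and $[y_{lo}, y_{hi}]$ vertically. For a negative-height
letter the glyph is drawn *upright* in its below-axis interval — shifted
down, never mirrored — so custom logos with depletion scores remain
readable.

## Color schemes

Eight named schemes are built in: `nucleotide`, `nucleotide2` and
`base_pairing` over the nucleic alphabets; `chemistry`, `chemistry2`,
`hydrophobicity`, `clustalx` and `taylor` over amino acids.
`hydrophobicity` is the one continuous scheme — Kyte–Doolittle values
rendered through a two-stop gradient; all others are discrete
letter-to-hex maps. The palettes follow the public conventions their
names reference (ClustalX's residue classes with the Jalview hex values,
Taylor's color wheel, chemistry classes), and are shipped as a plain
TSV resource (`inst/extdata/color_schemes.tsv`) so they can be audited
or extended. One anchor is fixed deliberately: `T` in the default
nucleotide scheme is `#D62839`, the value the alignment layer's
canonical worked example exposes. Letters a scheme does not map get a
neutral fallback grey (`#808080`); gap tiles use a paler neutral
(`#F0F0F0`) so "no residue" and "unmapped residue" stay visually
distinct.

Custom schemes come from `make_col_scheme()` — exactly one of `colors`
(discrete) or `values` (continuous). Per-*position* coloring, which no
static scheme can express, is done by editing the drawing table:
`mutate_layer(layer, letter = "R", position = 1, col = "#FF0000")`
recolors just those records, leaving geometry untouched.

## The three layers and their tables

Every layer exposes its drawing data publicly; the table *is* the
contract with the renderer, and editing it is supported, not a hack.

* `logo_layer()$data`: one row per outline point — `letter`, `position`,
  `piece`, `order`, `x`, `y`, `seq_group`, `col`/`value`, `group`,
  `poly_id`.
* `align_layer()$bg_data`: one row per tile — `letter`, `position`,
  `y_index`, `x` (= position), `y` (= `y_index` − 0.5), `width` (1),
  `height` (1), `seq_group`, plus `col` and `group` only in BACKGROUND
  mode. The letter overlay (`letter_data`) is omitted entirely in
  no-letter mode. Row 1 is the first input sequence; the rendered y
  axis is reversed so it reads at the top, the conventional MSA
  orientation (the `y = y_index - 0.5` relation is fixed; the display
  direction was a free choice). In BACKGROUND mode glyph ink is black
  or white by a relative-luminance threshold of 0.5, for legibility on
  dark tiles.
* `bar_layer()$bar_data`: one row per stacked segment — `letter`,
  `position`, `y_lo`, `y_hi`, `x`, `width`, `seq_group`,
  `col`/`value`, `group`. The default statistic is `count` (column
  totals equal the number of gap-free sequences), with `proportion` as
  the normalized option; the histogram's segments follow exactly the
  logo stacking order. Glyph labels are suppressed in segments shorter
  than 5% of their column — a pure legibility threshold, with no
  statistical meaning.

Named-list input produces one facet panel per key, in insertion order
(`seq_group` is a factor levelled accordingly); flat input yields the
single panel `"1"`.

`compose_layers()` puts several layers into one coordinate frame by
shifting each by a y offset and concatenating their primitives
(polygons and rectangles) with a layer tag — the standard trick for a
logo summarizing the alignment drawn directly beneath it. Inputs are
never mutated; continuous fills are resolved to hex through their
gradient at composition time so one identity fill scale serves the
whole figure.

```{r compose-example}
seqs <- simulate_sequences("TGACTCA", n = 8, mutation_rate = 0.15,
                           seed = 42)
comp <- compose_layers(
  list(aln = align_layer(seqs), logo = logo_layer(seqs, method = "bits")),
  offsets = c(0, length(seqs$sequences) + 0.5))
seq_plot(comp)
```

## Theme and axes

`theme_seq()` is the plain presentation layer: white background, no
grid, visible axis text, legend hidden by default (discrete letter
colors are redundant with the glyphs; continuous-gradient figures
re-enable it). It composes like any ggplot2 theme, so later user
`theme()` calls win. `axis_metadata()` exposes each layer's scale
conventions — integer x breaks at 1..L, the y label implied by the
method (`"bits"`, `"probability"`, the bar statistic, or none for
custom logos, where the units are the caller's), and the reversed
row-indexed y axis for alignments. Theme and scales never touch the
drawing tables; presentation and data stay separated.

## Synthetic example data — what it does and does not show

`example_data()` returns three keyed collections: `dna_pfms` and
`dna_seqs` (transcription-factor-style motifs) and `aa_seqs`
(kinase-substrate-style 15-mer windows). All of it is generated in code
by `simulate_sequences()` around documented consensus strings — e.g.
the AP-1-like `TGACTCA` and E-box-like `CACGTGAC` motifs at mutation
rate 0.15 with 50 sequences, and phosphosite-like amino-acid windows at
rate 0.3 with 40 sequences — under fixed seeds, with `SYN`-prefixed
labels to make the synthetic provenance explicit. No motif-database
content is redistributed.

The simulator's model is deliberately simple: independent positions,
a single consensus letter per column, uniform substitution among the
other letters. Real motifs have correlated positions, position-specific
substitution preferences, and mixed-composition columns. Passing tests
on these fixtures therefore demonstrates the *computational* pipeline —
tallying, normalization, information content, stacking, placement,
coloring, faceting, determinism — not biological realism of any
particular rendered motif.

## Numerical choices and degenerate inputs

* Probability-column normalization is checked to $10^{-9}$; entropy uses
  $0 \log 0 = 0$; the correction clamps $IC$ at 0.
* All-gap columns render empty everywhere (logo: no letters; bar: no
  segments; alignment: pale tiles) rather than erroring.
* Zero-height letters emit no stacked interval; a zero-height glyph
  placement is a degenerate zero-area polygon that draws nothing.
* Problem sizes in the checks were chosen to exercise the properties
  densely while keeping the default suite quick: 1,000 random matrices
  for normalization, hundreds of random columns against the brute-force
  stacking oracle, a 2,000-sequence simulation for the binomial
  calibration check.
* Seeds: `simulate_sequences()` requires one and restores the caller's
  RNG stream afterwards, so using the simulator never silently perturbs
  a user's session randomness.

## Known limitations

* No per-letter background frequencies (relative-entropy logos) and no
  probabilistic treatment of degenerate IUPAC codes; such letters are
  either ordinary alphabet members or errors.
* One glyph per character: no kerning, ligatures or right-to-left
  scripts; stacks are fixed-width per position.
* The alignment layer draws no margin annotations (labels, trees,
  consensus rows); compose with ordinary ggplot2 layers for those.
* Palettes are conventional, not optimized for color-vision deficiency;
  supply a custom scheme where that matters.
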