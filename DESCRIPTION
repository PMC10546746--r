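Package: seqgrammar
Title: Grammar-of-Graphics Sequence Logos, Alignment Diagrams and
    Sequence Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sequence logos (probability, information-bits and
    custom-height modes), multiple-sequence-alignment tile diagrams and
    per-position stacked sequence histograms as composable ggplot2
    layers. Every layer exposes a documented tidy drawing table that can
    be inspected, mutated record by record, and recombined with other
    layers in one coordinate system. Includes a catalog of 15 built-in
    glyph-outline fonts, 8 named color schemes for nucleic-acid and
    amino-acid alphabets, readers for FASTA alignments and JASPAR-style
    position frequency matrices, a seedable sequence simulator for
    reproducible fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    tibble,
    Biostrings,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
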