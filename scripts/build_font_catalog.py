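#!/usr/bin/env python
"""Build-time generator for the glyph-outline catalog under inst/extdata/fonts/.

Flattens the bezier outlines of 15 openly licensed font faces (DejaVu and
STIX families, as shipped with matplotlib) into polygon outlines, simplifies
them at a fixed chord tolerance, normalizes each glyph to a tight [0,1]^2
box and writes one columnar text file per face:

    # lines starting with '# ' (hash + space) are metadata/comments
    <char>\t<piece>\t<x0,y0 x1,y1 ...>

Coordinates are integers on a 0..1000 grid (divide by 1000 to recover unit
coordinates). Pieces are contiguous sub-paths (outer contours and holes);
the renderer fills them with the even-odd rule.

This script is NOT needed at package run time; the generated catalog files
are shipped with the package. Re-run it only to regenerate the catalog.
"""
import os
import sys

import numpy as np
import matplotlib
from matplotlib.textpath import TextPath
from matplotlib.font_manager import FontProperties
from shapely.geometry import LineString

EM = 100.0           # render size passed to TextPath
TOL = 1.5            # chord/simplification tolerance, units of EM/100 (1.5% of em)
GRID = 1000          # quantization grid for the unit box
CHARS = [chr(c) for c in range(33, 127)]  # printable ASCII minus space

FDIR = os.path.join(os.path.dirname(matplotlib.__file__), "mpl-data", "fonts", "ttf")

# catalog name -> (source ttf, human-readable source description)
FACES = {
    "sans_bold":         ("DejaVuSans-Bold.ttf",         "DejaVu Sans Bold"),
    "sans":              ("DejaVuSans.ttf",              "DejaVu Sans"),
    "sans_italic":       ("DejaVuSans-Oblique.ttf",      "DejaVu Sans Oblique"),
    "sans_bold_italic":  ("DejaVuSans-BoldOblique.ttf",  "DejaVu Sans Bold Oblique"),
    "serif":             ("DejaVuSerif.ttf",             "DejaVu Serif"),
    "serif_bold":        ("DejaVuSerif-Bold.ttf",        "DejaVu Serif Bold"),
    "serif_italic":      ("DejaVuSerif-Italic.ttf",      "DejaVu Serif Italic"),
    "serif_bold_italic": ("DejaVuSerif-BoldItalic.ttf",  "DejaVu Serif Bold Italic"),
    "mono":              ("DejaVuSansMono.ttf",          "DejaVu Sans Mono"),
    "mono_bold":         ("DejaVuSansMono-Bold.ttf",     "DejaVu Sans Mono Bold"),
    "mono_italic":       ("DejaVuSansMono-Oblique.ttf",  "DejaVu Sans Mono Oblique"),
    "mono_bold_italic":  ("DejaVuSansMono-BoldOblique.ttf", "DejaVu Sans Mono Bold Oblique"),
    "stix":              ("STIXGeneral.ttf",             "STIX General"),
    "stix_bold":         ("STIXGeneralBol.ttf",          "STIX General Bold"),
    "stix_italic":       ("STIXGeneralItalic.ttf",       "STIX General Italic"),
}


def glyph_pieces(ch, prop):
    tp = TextPath((0, 0), ch, size=EM, prop=prop)
    pieces = []
    for poly in tp.to_polygons():
        poly = np.asarray(poly, dtype=float)
        if len(poly) < 3:
            continue
        ring = LineString(np.vstack([poly, poly[:1]]))
        simp = np.asarray(ring.simplify(TOL, preserve_topology=False).coords)[:-1]
        if len(simp) >= 3:
            pieces.append(simp)
    return pieces


def quantize(pieces):
    allp = np.vstack(pieces)
    mn, mx = allp.min(axis=0), allp.max(axis=0)
    span = np.where(mx - mn > 0, mx - mn, 1.0)
    out = []
    for pts in pieces:
        q = np.round((pts - mn) / span * GRID).astype(int)
        keep = np.ones(len(q), dtype=bool)       # drop consecutive duplicates
        keep[1:] = (np.diff(q, axis=0) != 0).any(axis=1)
        q = q[keep]
        if len(q) >= 3:
            out.append(q)
    return out


def main(outdir):
    os.makedirs(outdir, exist_ok=True)
    total = 0
    for name, (ttf, desc) in FACES.items():
        prop = FontProperties(fname=os.path.join(FDIR, ttf))
        lines = [
            f"# glyph outline catalog: {name}",
            f"# source face: {desc} (open license: DejaVu/Bitstream Vera or SIL OFL for STIX)",
            f"# flatten tolerance: {TOL}% of em; coordinate grid: 0..{GRID} (divide by {GRID})",
            "# format: char<TAB>piece<TAB>x,y pairs separated by spaces; even-odd fill",
        ]
        for ch in CHARS:
            pieces = glyph_pieces(ch, prop)
            if not pieces:
                sys.exit(f"ERROR: {name} has no outline for {ch!r}")
            for i, q in enumerate(quantize(pieces), start=1):
                pts = " ".join(f"{x},{y}" for x, y in q)
                lines.append(f"{ch}\t{i}\t{pts}")
        path = os.path.join(outdir, name + ".txt")
        with open(path, "w") as fh:
            fh.write("\n".join(lines) + "\n")
        sz = os.path.getsize(path)
        total += sz
        print(f"{name:20s} {sz/1024:6.1f} KB")
    print(f"{'TOTAL':20s} {total/1024:6.1f} KB")


if __name__ == "__main__":
    main(sys.argv[1] if len(sys.argv) > 1 else "inst/extdata/fonts")
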