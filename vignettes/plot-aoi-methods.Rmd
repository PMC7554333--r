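---
title: "Building plot-level AOI shapefiles: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building plot-level AOI shapefiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plotshp)
```

## The problem

Plot-level extraction of remote-sensing data (plant height, canopy cover,
vegetation indices) from UAS orthomosaics needs one georeferenced polygon —
an area of interest, AOI — per experimental plot, carrying the plot's unique
identifier so measurements trace back to the genotype or treatment planted
there. Trials routinely contain hundreds to thousands of plots, so the
polygons must be generated, not drawn. `plotshp` builds the full polygon set
from three things a field researcher already has:

1. the **experimental-design table** (columns `Plot`, `Barcode`, `Range`,
   `Row`): which plot sits in which cell of the design matrix;
2. an **A-B line**: two surveyed UTM points that anchor the grid and give the
   field's deviation from north-south orientation;
3. the **plot and buffer dimensions** of the trial.

## Geometric model

All geometry is planar, in projected UTM meters; no geodesic corrections are
applied, which is consistent with the tool's UTM-only input contract
(geographic coordinates must be projected before use — that transformation
is out of scope here).

The field is first laid out in an unrotated local frame. The design matrix
is read like a book from bottom to top, left to right: `Row` indexes planted
rows across the field (local x), `Range` indexes plot rows along the field
(local y). Row and range numbering is always renumbered to begin at one
before any geometry is built, preserving gaps; this matters for the stagger
start row (see below). Cell (range *r*, row *c*) occupies

$$x \in [(c-1)\,\texttt{rowspc},\; c\,\texttt{rowspc}], \qquad
  y \in [(r-1)\,\texttt{rangespc},\; r\,\texttt{rangespc}].$$

The A point is the local origin: the front-left corner of the first plot, in
the middle of the preceding alley and of the inter-row space left of row
one. The bearing of the field is the clockwise-from-north angle of the A→B
direction, $\theta = \operatorname{atan2}(\Delta E, \Delta N)$, and the
local-to-UTM map is the rigid motion

$$E = E_A + x\cos\theta + y\sin\theta, \qquad
  N = N_A - x\sin\theta + y\cos\theta,$$

so local +y runs along A→B and local +x runs perpendicular, to the right
when facing B — rows extend to the right of the A-B line. This handedness is
encoded once, in `local_to_utm()`.

## Parameters

All four dimensions are given in `unit` (`"feet"`, the default, or
`"meter"`; feet convert with the exact international foot, 0.3048 m) and are
converted to meters once.

| parameter | default | meaning |
|---|---|---|
| `rowspc` | 2.5 ft (0.76 m) | width of one planted row (row/column spacing) |
| `rangespc` | 25 ft (7.62 m) | plot length including half an alley at each end |
| `rowbuf` | 0.1 ft (0.03 m) | removed from *both* sides of `rowspc` for the buffer ring |
| `rangebuf` | 2 ft (0.61 m) | removed from *both* ends of `rangespc` for the buffer ring |

Because buffers are removed from both ends, a 1.22 m alley is excluded
entirely by `rangebuf = 0.61` m. Defaults fit the maize trials the tool grew
out of; they will almost never fit another study and should always be set.

Multi-row plots are declared with `nrowplot = n`: the table then carries one
record per planted row, with the barcode repeated across the `n` adjacent
rows of each plot (barcodes must be unique across plots when
`nrowplot = 1`). Units are formed as consecutive row blocks
$[1..n], [n+1..2n], \dots$ within each range — the natural reading of
"adjacent rows", validated against barcode identity so a mis-specified
`nrowplot` fails loudly rather than silently regrouping. With
`multirowind = FALSE` the unit becomes one merged polygon spanning all its
rows; with `TRUE`, one polygon per row, unique IDs suffixed `_1`, `_2`, ...
left to right. `plotsubset = n` removes `n` rows from each side of the unit
first (interior-row extraction for competition-free yield rows); subsetting
precedes merging, so a six-row plot with `plotsubset = 2` yields either the
two inner rows individually or one two-row polygon.

A planter **stagger** `c(i, j, k)` models fields where alternating planter
passes are displaced along-field: starting at (renumbered) row `i`, passes
of `j` rows alternate between an offset of `k` (in `unit`, positive toward
the back of the field) and none. Whether the original tool shifts every
pass after row `i` or alternates is not documented; the alternating rule
matches the depicted planter-pass pattern and is isolated in
`stagger_offset()` so it can be swapped in one place. Merged plots whose
rows would straddle differently-offset passes are a fatal error — stagger
combines with merging only when plots align with planter passes. Negative
`k` is permitted and shifts toward the front.

## Buffered rings

The buffer ring of a polygon is its full ring contracted by `rowbuf` per
side and `rangebuf` per end, center preserved. For merged multi-row plots
the contraction applies to the merged outer extent, not per interior row:
buffers exist to separate *plot boundaries* and to drop bare soil at plot
edges, and interior row gaps inside one plot are neither. Parameters are
validated so the buffered rectangle always has positive area
(`2*rowbuf < rowspc`, `2*rangebuf < rangespc`).

## Coordinate reference system and output

With a `UTMzone` (and `Hemisphere`, default `"N"`), polygons are tagged
WGS-84 / UTM: EPSG 32600 + zone (north) or 32700 + zone (south), and a WKT1
`.prj` sidecar is written. WGS-84 is assumed because it is what UAS GPS
workflows produce; other datums can be accommodated by omitting the zone and
assigning a CRS in GIS afterwards. Without a zone the shapefiles carry no
CRS at all.

Two ESRI shapefile families are written — `<outfile>` from the full rings
and `<outfile>_buffer` from the buffered rings — each with `.shp`, `.shx`
and `.dbf` (and `.prj` when a CRS is present). The writer emits shape type 5
(Polygon), one clockwise, closed outer ring per record, record payloads
little-endian and header lengths in 16-bit words, per the ESRI
specification; the attribute table (Plot, Barcode, Range, Row, and Field
when a trial label is given) goes through `foreign::write.dbf`. Barcodes are
limited to 64 characters; longer values are a fatal error rather than a
silent truncation. Optional PDF previews (`SquarePlot` for the local frame,
`RotatePlot` for UTM) overlay full rings in black and buffer rings in red
with their unique IDs for rapid accuracy assessment.

## Numerical choices and degenerate inputs

* Output order is deterministic — units by (range, leftmost row) ascending —
  so identical inputs give byte-identical `.dbf` and numerically identical
  `.shp` files; there is no randomness anywhere in the pipeline.
* A coincident A and B point is a fatal error (the bearing is undefined);
  the bearing is otherwise exact in the full `(-π, π]` range, so fields may
  point any direction.
* Duplicate `(Range, Row)` cells are fatal; cells simply absent from the
  table produce no polygon, since real trials are often ragged rectangles.
* Suffix numbering after subsetting counts only the emitted polygons,
  left to right from `_1`.
* Column-name matching is exact and case-sensitive (`"Plot"`, `"Barcode"`,
  `"Range"`, `"Row"`).
* Checking that rotation preserves shoelace areas at UTM magnitudes
  (~10^6 m) requires centering the ring before the shoelace sum; the naive
  form loses about six digits to cancellation. This arises only in
  verification code — the pipeline itself never computes areas.

## What the synthetic designs do and do not cover

`make_design()` generates rectangular design tables with serpentine or
row-major plot numbering and repeated barcodes for multi-row plots — the
structure of real seed-preparation files. `worked_examples()` bundles
eight ready-made scenarios on six-row, two-row and staggered fields
(including the pair showing how the stagger start row shifts from 5 to 3
when two border rows are dropped from the table). The verification suite
runs these at desk scale — grids up to a few hundred polygons, 1000 random
bearings for the isometry checks — which exercises every code path in well
under a minute. What synthetic designs cannot show: whether a *surveyed*
A-B line matches a particular orthomosaic (stitching and orthorectification
error is a property of the imagery, assessed visually with the previews),
and whether the declared dimensions match what the planter actually did.
Passing tests certify the geometry downstream of the inputs, not the
inputs.

## Known limitations

* Rectangles only, on a uniform grid: no per-plot dimension overrides, no
  trapezoidal or curved plots.
* No reprojection: inputs must already be UTM.
* One stagger rule (alternating passes); fields staggered in some other
  systematic pattern need their table pre-shifted or the rule swapped in
  `stagger_offset()`.
* ESRI shapefile and PDF are the only outputs; GeoJSON/GeoPackage would be
  a small addition but is deliberately out of scope.
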