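# plotshp

Georeferenced multi-polygon ESRI shapefiles for agricultural research
plots.

Plot-based research programs extract remote-sensing measurements (plant
height, canopy cover, vegetation indices) from UAS orthomosaics one plot at
a time, through a polygon area-of-interest per plot that carries the plot's
unique barcode. Drawing thousands of such polygons by hand, in the right
rotation, with the right attributes, is the bottleneck this package
removes: it generates the entire polygon set from the trial's
experimental-design table, two surveyed UTM points, and the plot
dimensions.

## The method

The design matrix (`Range` along the field, `Row` across it, read like a
book from bottom to top, left to right) is laid out on a local grid with
cell (r, c) spanning `x ∈ [(c−1)·rowspc, c·rowspc]`,
`y ∈ [(r−1)·rangespc, r·rangespc]`. An A-B line — point A surveyed at the
front-left corner of the first plot, B further along the same inter-row
space — gives the field bearing `θ = atan2(ΔE, ΔN)` (clockwise from grid
north), and every corner is mapped into UTM by the rigid motion

    E = E_A + x·cosθ + y·sinθ
    N = N_A − x·sinθ + y·cosθ

Each plot gets two axis-aligned rectangles: the full plot, and a buffered
copy inset by `rowbuf` on each side and `rangebuf` on each end (so a
1.22 m alley disappears with `rangebuf = 0.61` m). Multi-row plots
(`nrowplot = n`, barcode repeated across the n adjacent rows) are either
merged into one polygon or emitted per row with `_1, _2, ...` suffixes;
`plotsubset` extracts interior rows; `stagger = c(i, j, k)` mirrors
alternating planter-pass offsets. Output is two shapefile families —
`<outfile>{.shp,.shx,.dbf,.prj}` (full plots) and `<outfile>_buffer.*`
(buffered) — in WGS-84 / UTM (EPSG 32600/32700 + zone), plus optional PDF
previews.

## Worked example

Four two-row plots in two ranges, merged, metric dimensions, UTM zone 14N
(College Station, TX):

```r
library(plotshp)
make_design(2, 4, nrowplot = 2, barcode_prefix = "CS17-G2F",
            path = "design.csv")
m <- plotshpcreate(A = c(746000, 3382000), B = c(746002, 3382100),
                   UTMzone = 14, infile = "design.csv",
                   outfile = "CS17-G2FE", nrowplot = 2, multirowind = FALSE,
                   rowspc = 0.76, rowbuf = 0.03, rangespc = 7.62,
                   rangebuf = 0.61, unit = "meter", field = "CS17-G2FE")
#> plotshp: 4 polygons, bearing 1.146 deg, EPSG 32614 -> CS17-G2FE{,_buffer}.shp
```

Four polygons: the 8-row table collapses to one merged polygon per
two-row plot. The bearing says the field leans 1.146° east of grid north
(B sits 2 m east over 100 m north). Reading the result back:

```r
rt <- read_shapefile("CS17-G2FE")
head(rt$attributes, 4)
#>   Plot      Barcode Range Row     Field
#> 1    1 CS17-G2F-001     1   1 CS17-G2FE
#> 2    2 CS17-G2F-002     1   3 CS17-G2FE
#> 3    3 CS17-G2F-003     2   1 CS17-G2FE
#> 4    4 CS17-G2F-004     2   3 CS17-G2FE
round(rt$rings[[1]], 3)
#>             x       y
#> [1,] 746000.0 3382000
#> [2,] 746000.2 3382008
#> [3,] 746001.7 3382008
#> [4,] 746001.5 3382000
#> [5,] 746000.0 3382000
```

The first ring starts at A (746000, 3382000), runs 7.62 m along the
tilted field axis (picking up the 0.15 m easting lean), and is 1.52 m
(2 × 0.76 m) wide — a closed, clockwise rectangle ready for QGIS/ArcGIS
zonal extraction. `CS17-G2FE_buffer.shp` holds the same plots inset by the
buffers.

A command-line wrapper with the same parameter names ships in
`inst/cli/plotshpcreate`:

```sh
Rscript inst/cli/plotshpcreate --infile design.csv --outfile CS17-G2FE \
    --A 746000,3382000 --B 746002,3382100 --UTMzone 14 \
    --unit meter --rowspc 0.76 --rangespc 7.62 --nrowplot 2
Rscript inst/cli/plotshpcreate --demo fig2C --outfile demo   # bundled scenarios
```

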