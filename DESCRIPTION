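Package: plotshp
Title: Georeferenced Multi-Polygon Shapefiles for Agricultural Research Plots
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds georeferenced ESRI multi-polygon shapefiles delimiting
    individual agricultural research plots (full-size and buffered areas of
    interest) from an experimental-design table, an A-B orientation line in
    UTM coordinates, and plot/buffer dimensions. Supports multi-row plot
    merging, interior-row subsetting, planter-pass stagger offsets, serpentine
    plot numbering, and WGS-84 UTM coordinate reference systems, producing
    attribute tables that trace each polygon back to its unique plot barcode
    for plot-level extraction from UAS orthomosaics in GIS software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    foreign,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
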