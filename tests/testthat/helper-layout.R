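# shared helpers: tiny layouts, shoelace area, rectangle overlap

shoelace <- function(ring) {
  # center first: naive shoelace on UTM-magnitude coordinates loses ~6
  # digits to cancellation
  x <- ring[, 1] - mean(ring[, 1]); y <- ring[, 2] - mean(ring[, 2])
  n <- nrow(ring)
  0.5 * abs(sum(x[-n] * y[-1] - x[-1] * y[-n]))
}

rect_overlap_area <- function(a, b) {
  w <- min(a[["xmax"]], b[["xmax"]]) - max(a[["xmin"]], b[["xmin"]])
  h <- min(a[["ymax"]], b[["ymax"]]) - max(a[["ymin"]], b[["ymin"]])
  max(0, w) * max(0, h)
}

# a metric-unit parameter set matching the published defaults
metric_params <- function(...) {
  grid_params(rowspc = 0.762, rangespc = 7.62, rowbuf = 0.03048,
              rangebuf = 0.6096, unit = "meter", ...)
}

simple_layout <- function(n_ranges = 2, n_rows = 2, ...) {
  df <- make_design(n_ranges, n_rows, barcode_prefix = "TST")
  build_layout(read_design(df), metric_params(...))
}

tmp_base <- function(name = "shp") {
  file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
}
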