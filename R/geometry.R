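#' Layout parameters for the plot grid
#'
#' Bundles and validates the plot/buffer dimensions and behaviour switches.
#' \code{rowspc} is the across-field width of a single planted row (crop row
#' spacing); \code{rangespc} is the along-field plot length including half the
#' alley on either end. \code{rowbuf}/\code{rangebuf} are removed from BOTH
#' sides/ends of the corresponding dimension to form the buffered polygon, so
#' a 1.22 m alley is excluded entirely with \code{rangebuf = 0.61} m.
#' Dimensions are interpreted in \code{unit} and converted to meters once, at
#' grid-construction time.
#'
#' @param rowspc row (column) spacing of a single row, > 0. Default 2.5 ft
#'   (0.76 m).
#' @param rangespc range (plot-length) spacing, > 0. Default 25 ft (7.62 m).
#' @param rowbuf distance removed from both sides of \code{rowspc}, >= 0.
#'   Default 0.1 ft (0.03 m).
#' @param rangebuf distance removed from both ends of \code{rangespc}, >= 0.
#'   Default 2 ft (0.61 m).
#' @param unit unit of measure for the four dimensions: \code{"feet"} or
#'   \code{"meter"}.
#' @param nrowplot number of adjacent rows constituting one plot/unique ID.
#' @param multirowind if \code{TRUE}, each row of a multi-row plot gets its
#'   own polygon with a \code{_n} suffix on the unique ID (numbered left to
#'   right); if \code{FALSE}, the rows are merged into one polygon.
#' @param plotsubset number of adjacent rows excluded from either side of a
#'   multi-row plot before polygons are built (interior-row extraction).
#' @param stagger \code{NULL} or \code{c(i, j, k)}: the (normalized) row where
#'   staggers start, the number of rows the planter sows in one pass, and the
#'   along-field stagger offset in \code{unit} (positive shifts toward the
#'   back of the field as seen from the A point).
#' @param field optional trial label written into the attribute table.
#' @param outfile output basename for shapefile/preview emission.
#' @return A validated \code{grid_params} list; dimension fields carry the
#'   declared unit, with metric twins \code{rowspc_m}, \code{rangespc_m},
#'   \code{rowbuf_m}, \code{rangebuf_m} and \code{stagger_m}.
#' @export
grid_params <- function(rowspc = 2.5, rangespc = 25, rowbuf = 0.1,
                        rangebuf = 2, unit = "feet", nrowplot = 1L,
                        multirowind = FALSE, plotsubset = 0L, stagger = NULL,
                        field = NULL, outfile = "plots") {
  stopifnot(is.numeric(rowspc), is.numeric(rangespc),
            is.numeric(rowbuf), is.numeric(rangebuf))
  if (rowspc <= 0 || rangespc <= 0) {
    stop("rowspc and rangespc must be > 0", call. = FALSE)
  }
  if (rowbuf < 0 || rangebuf < 0) {
    stop("rowbuf and rangebuf must be >= 0", call. = FALSE)
  }
  if (2 * rowbuf >= rowspc || 2 * rangebuf >= rangespc) {
    stop("buffers leave no area: need 2*rowbuf < rowspc and ",
         "2*rangebuf < rangespc", call. = FALSE)
  }
  nrowplot <- as.integer(nrowplot)
  plotsubset <- as.integer(plotsubset)
  if (nrowplot < 1L) stop("nrowplot must be >= 1", call. = FALSE)
  if (plotsubset < 0L) stop("plotsubset must be >= 0", call. = FALSE)
  if (plotsubset > 0L && 2L * plotsubset >= nrowplot) {
    stop("plotsubset removes every row: need 2*plotsubset < nrowplot",
         call. = FALSE)
  }
  if (!is.null(stagger)) {
    if (!is.numeric(stagger) || length(stagger) != 3L) {
      stop("stagger must be NULL or a numeric vector c(i, j, k)",
           call. = FALSE)
    }
    if (stagger[1] < 1 || stagger[2] < 1) {
      stop("stagger start row i and pass width j must be >= 1", call. = FALSE)
    }
  }
  p <- list(rowspc = rowspc, rangespc = rangespc, rowbuf = rowbuf,
            rangebuf = rangebuf, unit = unit, nrowplot = nrowplot,
            multirowind = isTRUE(multirowind), plotsubset = plotsubset,
            stagger = stagger, field = field, outfile = outfile)
  p$rowspc_m <- to_meters(rowspc, unit)
  p$rangespc_m <- to_meters(rangespc, unit)
  p$rowbuf_m <- to_meters(rowbuf, unit)
  p$rangebuf_m <- to_meters(rangebuf, unit)
  if (!is.null(stagger)) {
    p$stagger_m <- c(stagger[1], stagger[2], to_meters(stagger[3], unit))
  } else {
    p$stagger_m <- NULL
  }
  class(p) <- "grid_params"
  p
}

#' Convert a length to meters
#'
#' @param value finite length (or vector of lengths).
#' @param unit \code{"feet"} or \code{"meter"}. Feet are converted with the
#'   exact international foot, 0.3048 m.
#' @return length in meters.
#' @export
to_meters <- function(value, unit) {
  if (!all(is.finite(value))) stop("length must be finite", call. = FALSE)
  switch(unit,
         meter = value,
         feet = value * 0.3048,
         stop("unknown unit '", unit, "': use \"feet\" or \"meter\"",
              call. = FALSE))
}

# axis-aligned rectangle: named numeric c(xmin, ymin, xmax, ymax)
rect_make <- function(xmin, ymin, xmax, ymax) {
  c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
}

#' Local-frame cell rectangle of a design-matrix cell
#'
#' The local frame has the A point at the origin: the front-left corner of
#' cell (range 1, row 1). x grows across the field with the row index, y grows
#' along the field with the range index.
#'
#' @param range_index,row_index normalized indices (>= 1).
#' @param rowspc_m,rangespc_m cell dimensions in meters.
#' @return rectangle \code{c(xmin, ymin, xmax, ymax)}.
#' @export
cell_rect <- function(range_index, row_index, rowspc_m, rangespc_m) {
  rect_make((row_index - 1) * rowspc_m, (range_index - 1) * rangespc_m,
            row_index * rowspc_m, range_index * rangespc_m)
}

#' Shrink a rectangle by per-axis buffers
#'
#' Contracts the x-interval by \code{rowbuf_m} on each side and the y-interval
#' by \code{rangebuf_m} on each end; the center is preserved.
#'
#' @param rect rectangle \code{c(xmin, ymin, xmax, ymax)}.
#' @param rowbuf_m,rangebuf_m buffer distances in meters.
#' @return the contracted rectangle.
#' @export
shrink_rect <- function(rect, rowbuf_m, rangebuf_m) {
  out <- rect_make(rect[["xmin"]] + rowbuf_m, rect[["ymin"]] + rangebuf_m,
                   rect[["xmax"]] - rowbuf_m, rect[["ymax"]] - rangebuf_m)
  if (out[["xmin"]] >= out[["xmax"]] || out[["ymin"]] >= out[["ymax"]]) {
    stop("buffers collapse the polygon to zero or negative area",
         call. = FALSE)
  }
  out
}

#' Along-field stagger offset of a row
#'
#' Planter passes of width \code{j} alternate: starting at (normalized) row
#' \code{i}, rows of every other pass are displaced \code{k_m} meters toward
#' the back of the field. Rows before \code{i} are never displaced; for row
#' \code{r >= i} the pass number is \code{floor((r - i) / j)} and even passes
#' carry the offset.
#'
#' @param row_index normalized row index.
#' @param stagger \code{c(i, j, k_m)} with \code{k_m} already in meters, or
#'   \code{NULL} for no stagger.
#' @return offset in meters (0 or \code{k_m}), added to both y-coordinates of
#'   the row's cells.
#' @export
stagger_offset <- function(row_index, stagger) {
  if (is.null(stagger)) return(0)
  i <- stagger[1]; j <- stagger[2]; k <- stagger[3]
  if (row_index < i) return(0)
  pass <- floor((row_index - i) / j)
  if (pass %% 2 == 0) k else 0
}

#' Build the polygon(s) of one plot unit
#'
#' Applies, in order: interior-row subsetting (drop \code{plotsubset} cells
#' from each side), per-row stagger offsets, and either merging into one
#' polygon spanning the surviving rows (\code{multirowind = FALSE}) or
#' emission of one polygon per surviving row with \code{_n} suffixes counted
#' left to right from 1 (\code{multirowind = TRUE}). The buffer ring is the
#' full ring contracted by (\code{rowbuf}, \code{rangebuf}); for a merged plot
#' the buffer applies to the merged outer extent, since interior row gaps are
#' not plot boundaries.
#'
#' @param unit a plot unit from [validate_barcodes()].
#' @param params a \code{grid_params}.
#' @return list of local polygons, each a list with \code{unique_id},
#'   \code{plot}, \code{barcode}, \code{range}, \code{row_first},
#'   \code{row_last}, \code{full} and \code{buffer} rectangles (meters,
#'   local frame).
#' @export
build_plot_unit <- function(unit, params) {
  rows <- sort(unit$rows)
  ps <- params$plotsubset
  if (ps > 0L) {
    if (2L * ps >= length(rows)) {
      stop("plotsubset = ", ps, " removes all rows of a ", length(rows),
           "-row plot", call. = FALSE)
    }
    rows <- rows[(ps + 1L):(length(rows) - ps)]
  }
  offs <- vapply(rows, stagger_offset, 0, stagger = params$stagger_m)
  cells <- lapply(seq_along(rows), function(idx) {
    r <- cell_rect(unit$range, rows[idx], params$rowspc_m, params$rangespc_m)
    r[c("ymin", "ymax")] <- r[c("ymin", "ymax")] + offs[idx]
    r
  })

  mk <- function(id, rect, row_first, row_last) {
    list(unique_id = id, plot = unit$plot, barcode = unit$barcode,
         range = unit$range, row_first = row_first, row_last = row_last,
         full = rect,
         buffer = shrink_rect(rect, params$rowbuf_m, params$rangebuf_m))
  }

  if (params$multirowind && params$nrowplot > 1L) {
    lapply(seq_along(rows), function(idx) {
      mk(paste0(unit$barcode, "_", idx), cells[[idx]], rows[idx], rows[idx])
    })
  } else if (length(rows) == 1L) {
    list(mk(unit$barcode, cells[[1]], rows[1], rows[1]))
  } else {
    if (length(unique(offs)) != 1L) {
      stop("rows of the multi-row plot '", unit$barcode, "' (range ",
           unit$range, ") fall in differently staggered planter passes; ",
           "merged plots must not be split across passes", call. = FALSE)
    }
    merged <- rect_make(cells[[1]][["xmin"]], cells[[1]][["ymin"]],
                        cells[[length(cells)]][["xmax"]],
                        cells[[1]][["ymax"]])
    list(mk(unit$barcode, merged, rows[1], rows[length(rows)]))
  }
}

#' Build the full local-frame layout
#'
#' Normalizes and groups the design table, then concatenates
#' [build_plot_unit()] over all plot units in deterministic order (by range,
#' then leftmost row).
#'
#' @param table a \code{design_table}.
#' @param params a \code{grid_params}.
#' @return list of local polygons (see [build_plot_unit()]).
#' @export
build_layout <- function(table, params) {
  stopifnot(inherits(params, "grid_params"))
  table <- normalize_indices(table)
  units <- validate_barcodes(table, params$nrowplot)
  out <- lapply(units, build_plot_unit, params = params)
  unlist(out, recursive = FALSE)
}
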