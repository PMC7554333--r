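#' Read an experimental-design table
#'
#' Reads the seed-preparation / experimental-design file that drives polygon
#' creation. The table must contain the four columns \code{"Plot"},
#' \code{"Barcode"}, \code{"Range"} and \code{"Row"} (matched case-sensitively,
#' exactly as quoted); any additional columns are permitted but ignored.
#' \code{Range} indexes the along-field rows of the plot design matrix and
#' \code{Row} the across-field planted rows, reading the field like a book from
#' bottom to top, left to right.
#'
#' @param path path to a delimited text file with a header row, or a
#'   \code{data.frame} already holding the four required columns.
#' @param delimiter field delimiter for file input (default \code{","}).
#' @return A \code{design_table}: a \code{data.frame} with integer columns
#'   \code{plot}, \code{range}, \code{row} and character column
#'   \code{barcode}, in the original file order, plus attributes
#'   \code{n_ranges} and \code{n_rows}.
#' @seealso [normalize_indices()], [validate_barcodes()], [make_design()]
#' @export
read_design <- function(path, delimiter = ",") {
  if (is.data.frame(path)) {
    raw <- path
  } else {
    if (!file.exists(path)) {
      stop("design file not found: ", path, call. = FALSE)
    }
    raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                             colClasses = "character", check.names = FALSE,
                             stringsAsFactors = FALSE, encoding = "UTF-8",
                             quote = "\"", comment.char = "")
  }
  required <- c("Plot", "Barcode", "Range", "Row")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("design table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("design table has no data rows", call. = FALSE)

  as_int <- function(col, name) {
    x <- suppressWarnings(as.numeric(as.character(raw[[col]])))
    bad <- which(is.na(x) | x != round(x))
    if (length(bad) > 0) {
      stop("non-integer value in column '", name, "' at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    as.integer(round(x))
  }
  tab <- data.frame(
    plot = as_int("Plot", "Plot"),
    barcode = as.character(raw[["Barcode"]]),
    range = as_int("Range", "Range"),
    row = as_int("Row", "Row"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(tab$barcode)) || any(!nzchar(trimws(tab$barcode)))) {
    stop("empty Barcode value at data row(s) ",
         paste(which(is.na(tab$barcode) | !nzchar(trimws(tab$barcode))),
               collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(tab[c("range", "row")])
  if (any(dup)) {
    d <- tab[dup, , drop = FALSE]
    stop("duplicate (Range, Row) cell(s): ",
         paste(sprintf("(%d,%d)", d$range, d$row), collapse = ", "),
         call. = FALSE)
  }
  as_design_table(tab)
}

as_design_table <- function(tab) {
  attr(tab, "n_ranges") <- max(tab$range)
  attr(tab, "n_rows") <- max(tab$row)
  class(tab) <- c("design_table", "data.frame")
  tab
}

#' Renumber ranges and rows to begin at one
#'
#' Shifts the \code{range} and \code{row} indices so that the minimum of each
#' becomes 1 (a minimum row of 3 becomes 1, 4 becomes 2, and so forth); the
#' relative spacing of indices, including any gaps, is preserved. Plot grids
#' are always built on normalized indices, which matters when deciding the
#' starting row of a planter stagger: the stagger start refers to the
#' renumbered rows, so it depends on whether border rows are present in the
#' input table.
#'
#' @param table a \code{design_table} from [read_design()].
#' @return The table with shifted indices. Idempotent.
#' @export
normalize_indices <- function(table) {
  stopifnot(inherits(table, "design_table"), nrow(table) > 0)
  table$range <- table$range - (min(table$range) - 1L)
  table$row <- table$row - (min(table$row) - 1L)
  as_design_table(table)
}

#' Group design rows into plot units and validate barcodes
#'
#' With \code{nrowplot = 1} every record is its own plot unit and barcodes
#' must be unique across all records. With \code{nrowplot = n > 1}, each range
#' is partitioned into blocks of \code{n} consecutive row indices
#' (rows 1..n, n+1..2n, ...), and the rows of a block must share one barcode;
#' repeated barcodes across the adjacent rows of a plot are how multi-row
#' plots are declared in the input file.
#'
#' @param table a normalized \code{design_table}.
#' @param nrowplot number of adjacent rows constituting one plot.
#' @return A list of plot units; each unit is a list with fields
#'   \code{barcode}, \code{plot}, \code{range} and \code{rows} (sorted row
#'   indices, left to right).
#' @export
validate_barcodes <- function(table, nrowplot = 1L) {
  stopifnot(inherits(table, "design_table"))
  nrowplot <- as.integer(nrowplot)
  if (is.na(nrowplot) || nrowplot < 1L) {
    stop("nrowplot must be a positive integer", call. = FALSE)
  }
  if (min(table$range) != 1L || min(table$row) != 1L) {
    stop("design table must be normalized (indices starting at 1) before ",
         "grouping; call normalize_indices()", call. = FALSE)
  }

  if (nrowplot == 1L) {
    dup <- unique(table$barcode[duplicated(table$barcode)])
    if (length(dup) > 0) {
      stop("barcodes must be unique when nrowplot = 1; duplicated: ",
           paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
    }
    units <- lapply(seq_len(nrow(table)), function(i) {
      list(barcode = table$barcode[i], plot = table$plot[i],
           range = table$range[i], rows = table$row[i])
    })
  } else {
    # block id within each range: rows 1..n -> 1, n+1..2n -> 2, ...
    key <- split(seq_len(nrow(table)),
                 list(range = table$range,
                      block = (table$row - 1L) %/% nrowplot),
                 drop = TRUE)
    units <- lapply(key, function(idx) {
      sub <- table[idx, , drop = FALSE]
      sub <- sub[order(sub$row), , drop = FALSE]
      rg <- sub$range[1]
      if (nrow(sub) != nrowplot) {
        stop("incomplete multi-row plot in range ", rg, ", rows ",
             paste(sub$row, collapse = ","), ": expected ", nrowplot,
             " adjacent rows, found ", nrow(sub), call. = FALSE)
      }
      if (length(unique(sub$barcode)) != 1L) {
        stop("barcodes differ within the multi-row plot at range ", rg,
             ", rows ", paste(sub$row, collapse = ","), ": ",
             paste(unique(sub$barcode), collapse = " / "), call. = FALSE)
      }
      list(barcode = sub$barcode[1], plot = sub$plot[1],
           range = rg, rows = sub$row)
    })
  }
  # deterministic order: by range, then leftmost row
  ord <- order(vapply(units, `[[`, 1L, "range"),
               vapply(units, function(u) min(u$rows), 1L))
  unname(units[ord])
}
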