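#' Generate a synthetic experimental-design table
#'
#' Builds a rectangular design matrix with the four required columns
#' (\code{Plot}, \code{Barcode}, \code{Range}, \code{Row}). Plot numbers are
#' assigned reading the field bottom to top; within a range they run left to
#' right, or alternate direction range by range when \code{serpentine} is
#' set (the numbering convention common in small-plot trials). Multi-row
#' plots repeat their plot number and barcode across the \code{nrowplot}
#' adjacent rows, as seed-preparation files do.
#'
#' @param n_ranges,n_rows grid dimensions.
#' @param nrowplot rows per plot; must divide \code{n_rows}.
#' @param barcode_prefix barcodes are \code{"<prefix>-%03d"} by plot number.
#' @param serpentine alternate numbering direction range by range.
#' @param path optional CSV path; when given the table is also written with
#'   exactly the four required headers.
#' @return a \code{data.frame} with columns \code{Plot}, \code{Barcode},
#'   \code{Range}, \code{Row}, one record per occupied cell, range-major.
#' @export
make_design <- function(n_ranges, n_rows, nrowplot = 1L,
                        barcode_prefix = "CS17-TST", serpentine = FALSE,
                        path = NULL) {
  n_ranges <- as.integer(n_ranges); n_rows <- as.integer(n_rows)
  nrowplot <- as.integer(nrowplot)
  stopifnot(n_ranges >= 1L, n_rows >= 1L, nrowplot >= 1L)
  if (n_rows %% nrowplot != 0L) {
    stop("n_rows (", n_rows, ") must be divisible by nrowplot (", nrowplot,
         ")", call. = FALSE)
  }
  units_per_range <- n_rows %/% nrowplot
  recs <- vector("list", n_ranges * n_rows)
  k <- 0L
  for (rg in seq_len(n_ranges)) {
    # unit order within the range: left-to-right, flipped on even ranges
    # when serpentine
    unit_order <- seq_len(units_per_range)
    if (serpentine && rg %% 2L == 0L) unit_order <- rev(unit_order)
    for (pos in seq_len(units_per_range)) {
      unit <- unit_order[pos]
      plot_no <- (rg - 1L) * units_per_range + pos
      barcode <- sprintf("%s-%03d", barcode_prefix, plot_no)
      for (sub in seq_len(nrowplot)) {
        k <- k + 1L
        recs[[k]] <- data.frame(
          Plot = plot_no, Barcode = barcode, Range = rg,
          Row = (unit - 1L) * nrowplot + sub, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, recs)
  df <- df[order(df$Range, df$Row), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  df
}

#' Ready-made worked-example scenarios
#'
#' Named argument lists for [plotshpcreate()] reproducing the documented
#' behaviours of the optional arguments on six-row and staggered fields:
#' \describe{
#'   \item{fig2A}{six-row plots, one polygon per row (\code{multirowind}).}
#'   \item{fig2B}{six-row plots merged to a single polygon each.}
#'   \item{fig2C}{interior two rows of each six-row plot, individually
#'     (\code{plotsubset = 2}).}
#'   \item{fig2D}{interior two rows merged to one polygon.}
#'   \item{fig2E}{staggered field, one polygon per row.}
#'   \item{fig2F}{staggered field of merged two-row plots (plots aligned
#'     with planter passes).}
#'   \item{fig3A}{12 rows including two border rows, stagger starting at
#'     row 5 of a four-row planter, 3.8 m offset.}
#'   \item{fig3B}{the same field without border rows in the table; the
#'     stagger start shifts to row 3.}
#' }
#' Each element is a complete argument list (design table inline as
#' \code{infile}); run one with \code{do.call(plotshpcreate, cfg)} after
#' setting \code{cfg$outfile}, or via the CLI \code{--demo} flag.
#'
#' @return named list of argument lists.
#' @export
worked_examples <- function() {
  A <- c(746000, 3382000)
  B <- c(746002, 3382100)  # slight deviation from due north
  base <- list(A = A, B = B, UTMzone = 14, Hemisphere = "N",
               unit = "meter", rowspc = 0.76, rowbuf = 0.03,
               rangespc = 7.62, rangebuf = 0.61,
               SquarePlot = FALSE, RotatePlot = FALSE,
               outfile = file.path(tempdir(), "plotshp_demo"))
  six <- make_design(2, 12, nrowplot = 6, barcode_prefix = "CS17-G2F")
  stag12 <- make_design(3, 12, nrowplot = 1, barcode_prefix = "CS17-STG")
  stag10 <- stag12[stag12$Row >= 3, , drop = FALSE]  # border rows excluded
  two <- make_design(2, 8, nrowplot = 2, barcode_prefix = "CS17-2RW")
  scen <- list(
    fig2A = c(list(infile = six, nrowplot = 6, multirowind = TRUE), base),
    fig2B = c(list(infile = six, nrowplot = 6, multirowind = FALSE), base),
    fig2C = c(list(infile = six, nrowplot = 6, multirowind = TRUE,
                   plotsubset = 2), base),
    fig2D = c(list(infile = six, nrowplot = 6, multirowind = FALSE,
                   plotsubset = 2), base),
    fig2E = c(list(infile = stag12, nrowplot = 1,
                   stagger = c(5, 4, 3.8)), base),
    fig2F = c(list(infile = two, nrowplot = 2, multirowind = FALSE,
                   stagger = c(1, 4, 3.8)), base),
    fig3A = c(list(infile = stag12, nrowplot = 1,
                   stagger = c(5, 4, 3.8)), base),
    fig3B = c(list(infile = stag10, nrowplot = 1,
                   stagger = c(3, 4, 3.8)), base)
  )
  scen
}
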