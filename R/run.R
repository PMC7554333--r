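#' Create georeferenced plot-AOI shapefiles for a field trial
#'
#' The main driver: reads the experimental-design table, renumbers ranges and
#' rows to begin at one, groups multi-row plots by barcode, builds the local
#' grid of full and buffered plot rectangles (with optional interior-row
#' subsetting and planter stagger), rotates and translates it into UTM using
#' the A-B line, and writes two ESRI shapefile families (full plots, and
#' buffered plots with \code{_buffer} appended to the basename) plus optional
#' PDF previews.
#'
#' Arguments mirror the tool's published parameter gallery; \code{A},
#' \code{B}, \code{infile} and \code{outfile} are mandatory.
#'
#' @param A,B numeric \code{c(easting, northing)} UTM coordinates of the A
#'   and B points. A sits at the front-left corner of the first plot; B lies
#'   further along the same inter-row space and fixes the field angle.
#' @param UTMzone UTM zone number (1-60); \code{NULL} leaves the shapefiles
#'   without a coordinate reference system (no \code{.prj}).
#' @param Hemisphere \code{"N"} (default) or \code{"S"}.
#' @param infile path to the design CSV or a data.frame with columns
#'   \code{Plot}, \code{Barcode}, \code{Range}, \code{Row}.
#' @param outfile output basename for all emitted files.
#' @param nrowplot,multirowind,rowspc,rowbuf,rangespc,rangebuf,stagger,plotsubset,field,unit
#'   layout parameters; see [grid_params()].
#' @param SquarePlot,RotatePlot write the unrotated / rotated PDF preview.
#' @param delimiter design-file delimiter.
#' @return (invisibly) a manifest list: \code{files} written,
#'   \code{n_polygons}, \code{bearing_deg}, \code{epsg} (or NA), and the
#'   \code{geo_polygon_set}.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' make_design(2, 2, barcode_prefix = "CS17-TST", path = csv)
#' out <- file.path(tempdir(), "demo")
#' m <- plotshpcreate(A = c(500000, 3000000), B = c(500000, 3000100),
#'                    UTMzone = 14, infile = csv, outfile = out,
#'                    SquarePlot = FALSE, RotatePlot = FALSE)
#' m$n_polygons
#' @export
plotshpcreate <- function(A = NULL, B = NULL, UTMzone = NULL,
                          Hemisphere = "N", infile = NULL, outfile = NULL,
                          nrowplot = 1, multirowind = FALSE, rowspc = 2.5,
                          rowbuf = 0.1, rangespc = 25, rangebuf = 2,
                          stagger = NULL, plotsubset = 0, field = NULL,
                          unit = "feet", SquarePlot = TRUE, RotatePlot = TRUE,
                          delimiter = ",") {
  for (nm in c("A", "B", "infile", "outfile")) {
    if (is.null(get(nm))) {
      stop("argument '", nm, "' is mandatory", call. = FALSE)
    }
  }
  params <- grid_params(rowspc = rowspc, rangespc = rangespc,
                        rowbuf = rowbuf, rangebuf = rangebuf, unit = unit,
                        nrowplot = nrowplot, multirowind = multirowind,
                        plotsubset = plotsubset, stagger = stagger,
                        field = field, outfile = outfile)
  ab <- ab_line(A, B, utm_zone = UTMzone, hemisphere = Hemisphere)
  table <- read_design(infile, delimiter = delimiter)
  layout <- build_layout(table, params)
  geo <- georeference(layout, ab)
  geo$field <- field
  files <- write_shapefiles(geo, outfile)
  files <- c(files, render_previews(geo, layout, square = SquarePlot,
                                    rotate = RotatePlot, basename = outfile))
  manifest <- list(files = files, n_polygons = length(geo$polygons),
                   bearing_deg = geo$theta * 180 / pi,
                   epsg = if (is.null(geo$crs)) NA_integer_ else geo$crs$epsg,
                   geo = geo)
  message(sprintf(
    "plotshp: %d polygons, bearing %.3f deg, EPSG %s -> %s{,_buffer}.shp",
    manifest$n_polygons, manifest$bearing_deg,
    ifelse(is.na(manifest$epsg), "NA", manifest$epsg), outfile))
  invisible(manifest)
}

parse_kv_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  vals
}

num_pair <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (length(v) != 2L || any(is.na(v))) {
    stop("expected \"easting,northing\", got: ", s, call. = FALSE)
  }
  v
}

num_triple <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (length(v) != 3L || any(is.na(v))) {
    stop("expected \"i,j,k\", got: ", s, call. = FALSE)
  }
  v
}

#' Command-line entry point
#'
#' Backs the \code{inst/cli/plotshpcreate} Rscript. Flags are named after the
#' function parameters (\code{--rowspc}, \code{--nrowplot}, ...); \code{--A}
#' and \code{--B} take \code{"easting,northing"}, \code{--stagger} takes
#' \code{"i,j,k"}. A key=value \code{--config} file may supply any flag, with
#' the command line taking precedence. \code{--demo <name>} runs a bundled
#' worked-example scenario (see [worked_examples()]).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 success, 1 data/processing error, 2 usage
#'   error.
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    A = "character", B = "character", UTMzone = "integer",
    Hemisphere = "character", infile = "character", outfile = "character",
    nrowplot = "integer", multirowind = "logical", rowspc = "double",
    rowbuf = "double", rangespc = "double", rangebuf = "double",
    stagger = "character", plotsubset = "integer", field = "character",
    unit = "character", SquarePlot = "logical", RotatePlot = "logical",
    delimiter = "character", config = "character", demo = "character",
    quiet = "logical"
  )
  opts <- list()
  i <- 1L
  usage <- function() {
    cat("usage: plotshpcreate --infile design.csv --outfile base",
        "--A e,n --B e,n [--UTMzone z] [--Hemisphere N|S]",
        "[--rowspc 2.5 --rowbuf 0.1 --rangespc 25 --rangebuf 2 --unit feet]",
        "[--nrowplot n --multirowind --plotsubset n --stagger i,j,k]",
        "[--field LABEL] [--SquarePlot T|F --RotatePlot T|F]",
        "[--config file] [--demo name] [--quiet]\n")
  }
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("-h", "--help")) { usage(); return(0L) }
    if (!startsWith(a, "--")) {
      message("usage error: unexpected argument '", a, "'"); usage()
      return(2L)
    }
    key <- substring(a, 3L)
    type <- spec[[key]]
    if (is.null(type)) {
      message("usage error: unknown flag --", key); usage()
      return(2L)
    }
    if (type == "logical" &&
        (i == length(args) || startsWith(args[i + 1L], "--"))) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) {
        message("usage error: --", key, " needs a value"); usage()
        return(2L)
      }
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  if (!is.null(opts$config)) {
    file_opts <- parse_kv_config(opts$config)
    for (k in names(file_opts)) {
      if (is.null(opts[[k]])) opts[[k]] <- file_opts[[k]]
    }
  }
  quiet <- isTRUE(opts$quiet) || identical(opts$quiet, "TRUE")

  status <- tryCatch({
    if (!is.null(opts$demo)) {
      cfgs <- worked_examples()
      if (!opts$demo %in% names(cfgs)) {
        message("usage error: unknown demo '", opts$demo, "'; available: ",
                paste(names(cfgs), collapse = ", "))
        return(2L)
      }
      cfg <- cfgs[[opts$demo]]
      if (!is.null(opts$outfile)) cfg$outfile <- opts$outfile
    } else {
      for (req in c("A", "B", "infile", "outfile")) {
        if (is.null(opts[[req]])) {
          message("usage error: --", req, " is mandatory"); usage()
          return(2L)
        }
      }
      coerce <- function(key, default) {
        v <- opts[[key]]
        if (is.null(v)) return(default)
        switch(spec[[key]],
               integer = as.integer(v),
               double = as.numeric(v),
               logical = as.logical(v),
               v)
      }
      cfg <- list(
        A = num_pair(opts$A), B = num_pair(opts$B),
        UTMzone = coerce("UTMzone", NULL),
        Hemisphere = coerce("Hemisphere", "N"),
        infile = opts$infile, outfile = opts$outfile,
        nrowplot = coerce("nrowplot", 1L),
        multirowind = coerce("multirowind", FALSE),
        rowspc = coerce("rowspc", 2.5), rowbuf = coerce("rowbuf", 0.1),
        rangespc = coerce("rangespc", 25), rangebuf = coerce("rangebuf", 2),
        stagger = if (is.null(opts$stagger)) NULL else
          num_triple(opts$stagger),
        plotsubset = coerce("plotsubset", 0L),
        field = coerce("field", NULL), unit = coerce("unit", "feet"),
        SquarePlot = coerce("SquarePlot", TRUE),
        RotatePlot = coerce("RotatePlot", TRUE),
        delimiter = coerce("delimiter", ","))
    }
    run_one <- function() do.call(plotshpcreate, cfg)
    manifest <- if (quiet) suppressMessages(run_one()) else run_one()
    if (!quiet) message("files written:\n  ",
                        paste(manifest$files, collapse = "\n  "))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
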