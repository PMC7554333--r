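# ESRI Shapefile emission. Layout follows the ESRI Shapefile Technical
# Description: big-endian file header fields (magic 9994, lengths in 16-bit
# words), little-endian record payloads, shape type 5 (Polygon), outer rings
# clockwise and closed. One rectangle ring per record, so every record payload
# is a fixed 128 bytes.

SHP_TYPE_POLYGON <- 5L

write_shp_pair <- function(rings, shp_path, shx_path) {
  n <- length(rings)
  all_xy <- do.call(rbind, rings)
  bbox <- c(min(all_xy[, 1]), min(all_xy[, 2]),
            max(all_xy[, 1]), max(all_xy[, 2]))
  content_bytes <- vapply(rings, function(r) {
    44L + 4L + 16L * nrow(r)  # type+box+counts, one part index, points
  }, 1L)
  shp_len_words <- (100L + sum(content_bytes + 8L)) %/% 2L
  shx_len_words <- (100L + 8L * n) %/% 2L

  header <- function(len_words) {
    con <- raw(0)
    c(writeBin(c(9994L, 0L, 0L, 0L, 0L, 0L, len_words), con,
               size = 4, endian = "big"),
      writeBin(c(1000L, SHP_TYPE_POLYGON), con, size = 4, endian = "little"),
      writeBin(c(bbox, 0, 0, 0, 0), con, size = 8, endian = "little"))
  }

  shp <- file(shp_path, "wb"); on.exit(close(shp), add = TRUE)
  shx <- file(shx_path, "wb"); on.exit(close(shx), add = TRUE)
  writeBin(header(shp_len_words), shp)
  writeBin(header(shx_len_words), shx)
  offset_words <- 50L
  for (i in seq_len(n)) {
    ring <- rings[[i]]
    writeBin(c(offset_words, content_bytes[i] %/% 2L), shx,
             size = 4, endian = "big")
    writeBin(c(i, content_bytes[i] %/% 2L), shp, size = 4, endian = "big")
    writeBin(SHP_TYPE_POLYGON, shp, size = 4, endian = "little")
    writeBin(c(min(ring[, 1]), min(ring[, 2]),
               max(ring[, 1]), max(ring[, 2])),
             shp, size = 8, endian = "little")
    writeBin(c(1L, nrow(ring)), shp, size = 4, endian = "little")
    writeBin(0L, shp, size = 4, endian = "little")  # part start index
    writeBin(as.vector(t(ring)), shp, size = 8, endian = "little")
    offset_words <- offset_words + 4L + content_bytes[i] %/% 2L
  }
  invisible(c(shp_path, shx_path))
}

attribute_table <- function(geo) {
  polys <- geo$polygons
  barcodes <- vapply(polys, `[[`, "", "unique_id")
  too_long <- which(nchar(barcodes, type = "bytes") > 64L)
  if (length(too_long) > 0) {
    stop("Barcode/unique ID exceeds the 64-character attribute field: ",
         paste(utils::head(barcodes[too_long], 5L), collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    Plot = vapply(polys, function(p) as.integer(p$plot), 1L),
    Barcode = barcodes,
    Range = vapply(polys, function(p) as.integer(p$range), 1L),
    Row = vapply(polys, function(p) as.integer(p$row_first), 1L),
    stringsAsFactors = FALSE
  )
  if (!is.null(geo$field)) df$Field <- as.character(geo$field)
  df
}

#' Write a georeferenced polygon set as ESRI shapefile families
#'
#' Emits two shapefile families: \code{<basename>.shp/.shx/.dbf} from the
#' full plot rings and \code{<basename>_buffer.shp/.shx/.dbf} from the
#' buffered rings. A \code{.prj} sidecar (WKT1) accompanies each family when
#' the set carries a coordinate reference system. Every record carries the
#' attributes Plot, Barcode (the unique ID, suffixed for individually emitted
#' multi-row plots), Range and Row, plus Field when a trial label was given.
#'
#' @param geo a \code{geo_polygon_set} from [georeference()]; an optional
#'   \code{field} element supplies the trial label.
#' @param basename output path prefix (directories must exist).
#' @return (invisibly) character vector of the files written.
#' @export
write_shapefiles <- function(geo, basename) {
  stopifnot(inherits(geo, "geo_polygon_set"), length(geo$polygons) > 0)
  df <- attribute_table(geo)
  written <- character(0)
  for (fam in c("full", "buffer")) {
    base <- if (fam == "full") basename else paste0(basename, "_buffer")
    rings <- lapply(geo$polygons, `[[`,
                    if (fam == "full") "full" else "buffer")
    write_shp_pair(rings, paste0(base, ".shp"), paste0(base, ".shx"))
    foreign::write.dbf(df, paste0(base, ".dbf"))
    written <- c(written, paste0(base, c(".shp", ".shx", ".dbf")))
    if (!is.null(geo$crs)) {
      writeLines(geo$crs$wkt, paste0(base, ".prj"))
      written <- c(written, paste0(base, ".prj"))
    }
  }
  invisible(written)
}

#' Read back one shapefile family
#'
#' Minimal reader for the polygon shapefiles this package writes, used for
#' verification and round-trip testing. Parses the \code{.shp} geometry and
#' the \code{.dbf} attribute table.
#'
#' @param basename path prefix of the family (no extension).
#' @return list with \code{shape_type}, \code{bbox} (xmin, ymin, xmax, ymax),
#'   \code{rings} (list of closed x/y matrices) and \code{attributes}
#'   (data.frame).
#' @export
read_shapefile <- function(basename) {
  shp_path <- paste0(basename, ".shp")
  if (!file.exists(shp_path)) stop("no such shapefile: ", shp_path,
                                   call. = FALSE)
  con <- file(shp_path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 9994L) stop("not a shapefile: bad magic number", call. = FALSE)
  invisible(readBin(con, "integer", 5, size = 4, endian = "big"))
  len_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # version
  shape_type <- readBin(con, "integer", 1, size = 4, endian = "little")
  bbox <- readBin(con, "double", 4, size = 8, endian = "little")
  invisible(readBin(con, "double", 4, size = 8, endian = "little")) # z/m
  rings <- list()
  bytes_read <- 100L
  while (bytes_read < 2L * len_words) {
    invisible(readBin(con, "integer", 1, size = 4, endian = "big")) # rec no
    clen <- readBin(con, "integer", 1, size = 4, endian = "big")
    invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # type
    invisible(readBin(con, "double", 4, size = 8, endian = "little"))  # box
    nparts <- readBin(con, "integer", 1, size = 4, endian = "little")
    npoints <- readBin(con, "integer", 1, size = 4, endian = "little")
    invisible(readBin(con, "integer", nparts, size = 4, endian = "little"))
    xy <- readBin(con, "double", 2L * npoints, size = 8, endian = "little")
    m <- matrix(xy, ncol = 2, byrow = TRUE)
    colnames(m) <- c("x", "y")
    rings[[length(rings) + 1L]] <- m
    bytes_read <- bytes_read + 8L + 2L * clen
  }
  attrs <- foreign::read.dbf(paste0(basename, ".dbf"), as.is = TRUE)
  list(shape_type = shape_type,
       bbox = c(xmin = bbox[1], ymin = bbox[2], xmax = bbox[3],
                ymax = bbox[4]),
       rings = rings, attributes = attrs)
}

draw_polys <- function(rings_full, rings_buffer, ids, main) {
  all_xy <- do.call(rbind, rings_full)
  graphics::plot(NA, xlim = range(all_xy[, 1]), ylim = range(all_xy[, 2]),
                 asp = 1, xlab = "x (m)", ylab = "y (m)", main = main)
  for (r in rings_full) graphics::polygon(r[, 1], r[, 2], border = "black")
  for (r in rings_buffer) graphics::polygon(r[, 1], r[, 2], border = "red")
  centers <- t(vapply(rings_full, function(r) {
    c(mean(r[1:4, 1]), mean(r[1:4, 2]))
  }, c(0, 0)))
  graphics::text(centers[, 1], centers[, 2], labels = ids, cex = 0.35,
                 srt = 90, col = "grey30")
}

#' Render PDF previews of the plot polygons
#'
#' Overlays full (black) and buffered (red) rings with their unique IDs for
#' rapid accuracy assessment, before and/or after rotation into UTM.
#'
#' @param geo a \code{geo_polygon_set} (used when \code{rotate} is TRUE).
#' @param layout the local-frame layout (used when \code{square} is TRUE).
#' @param square write \code{<basename>_SquarePlots.pdf} of the unrotated
#'   local-frame polygons.
#' @param rotate write \code{<basename>_RotatePlots.pdf} of the UTM polygons.
#' @param basename output path prefix.
#' @return (invisibly) character vector of the files written (may be empty).
#' @export
render_previews <- function(geo, layout, square = TRUE, rotate = TRUE,
                            basename = "plots") {
  written <- character(0)
  if (isTRUE(square)) {
    path <- paste0(basename, "_SquarePlots.pdf")
    grDevices::pdf(path, width = 8, height = 10)
    draw_polys(lapply(layout, function(p) rect_ring(p$full)),
               lapply(layout, function(p) rect_ring(p$buffer)),
               vapply(layout, `[[`, "", "unique_id"),
               "Plot polygons (local frame)")
    grDevices::dev.off()
    written <- c(written, path)
  }
  if (isTRUE(rotate)) {
    path <- paste0(basename, "_RotatePlots.pdf")
    grDevices::pdf(path, width = 8, height = 10)
    draw_polys(lapply(geo$polygons, `[[`, "full"),
               lapply(geo$polygons, `[[`, "buffer"),
               vapply(geo$polygons, `[[`, "", "unique_id"),
               "Plot polygons (UTM)")
    grDevices::dev.off()
    written <- c(written, path)
  }
  invisible(written)
}
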