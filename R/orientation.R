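#' A-B orientation line in UTM coordinates
#'
#' The A point must lie at the front-left corner of the first plot of the
#' design matrix (reading the field like a book, bottom to top and left to
#' right): in the middle of the preceding alley and in the middle of the
#' inter-row space left of the first row. The B point lies anywhere further
#' along that same inter-row space; it fixes the field's deviation from
#' north-south orientation.
#'
#' @param A,B numeric \code{c(easting, northing)} in UTM meters.
#' @param utm_zone UTM zone number 1-60, or \code{NULL} to leave the output
#'   without a coordinate reference system.
#' @param hemisphere \code{"N"} or \code{"S"}.
#' @return an \code{ab_line} object.
#' @export
ab_line <- function(A, B, utm_zone = NULL, hemisphere = "N") {
  stopifnot(is.numeric(A), length(A) == 2L, is.numeric(B), length(B) == 2L)
  if (!all(is.finite(c(A, B)))) stop("A and B must be finite", call. = FALSE)
  if (identical(unname(A), unname(B)) ||
      sqrt(sum((B - A)^2)) == 0) {
    stop("degenerate A-B line: A and B coincide", call. = FALSE)
  }
  if (!hemisphere %in% c("N", "S")) {
    stop("hemisphere must be \"N\" or \"S\"", call. = FALSE)
  }
  if (!is.null(utm_zone)) {
    utm_zone <- as.integer(utm_zone)
    if (is.na(utm_zone) || utm_zone < 1L || utm_zone > 60L) {
      stop("UTM zone must be an integer in 1..60", call. = FALSE)
    }
  }
  structure(list(a_easting = A[1], a_northing = A[2],
                 b_easting = B[1], b_northing = B[2],
                 utm_zone = utm_zone, hemisphere = hemisphere),
            class = "ab_line")
}

#' Field bearing of the A-B line
#'
#' @param ab an \code{ab_line}.
#' @return angle in radians, clockwise from grid north, of the A-to-B
#'   direction; 0 iff A-B points due grid north. Range (-pi, pi].
#' @export
bearing <- function(ab) {
  stopifnot(inherits(ab, "ab_line"))
  atan2(ab$b_easting - ab$a_easting, ab$b_northing - ab$a_northing)
}

#' Map a local-frame point into UTM
#'
#' The local frame is anchored at A with +y running along A-to-B and +x
#' perpendicular, to the right when facing from A toward B (rows extend right
#' of the A-B line). The map is the planar isometry
#' \deqn{E = E_A + x\cos\theta + y\sin\theta,\quad
#'       N = N_A - x\sin\theta + y\cos\theta}
#' with \eqn{\theta} the clockwise-from-north bearing.
#'
#' @param x,y local coordinates in meters (vectors of equal length).
#' @param ab an \code{ab_line}.
#' @param theta optional precomputed bearing (radians); defaults to
#'   \code{bearing(ab)}.
#' @return two-column matrix \code{cbind(easting, northing)}.
#' @export
local_to_utm <- function(x, y, ab, theta = bearing(ab)) {
  ct <- cos(theta); st <- sin(theta)
  cbind(easting = ab$a_easting + x * ct + y * st,
        northing = ab$a_northing - x * st + y * ct)
}

#' EPSG code and WKT for a WGS-84 UTM zone
#'
#' Northern-hemisphere zones map to EPSG 32600 + zone, southern to
#' 32700 + zone. The WKT1 text is suitable for an ESRI \code{.prj} sidecar.
#'
#' @param utm_zone integer 1-60.
#' @param hemisphere \code{"N"} or \code{"S"}.
#' @return list with \code{epsg} (integer) and \code{wkt} (character).
#' @export
epsg_for_zone <- function(utm_zone, hemisphere = "N") {
  utm_zone <- as.integer(utm_zone)
  if (is.na(utm_zone) || utm_zone < 1L || utm_zone > 60L) {
    stop("UTM zone must be an integer in 1..60", call. = FALSE)
  }
  if (!hemisphere %in% c("N", "S")) {
    stop("hemisphere must be \"N\" or \"S\"", call. = FALSE)
  }
  epsg <- if (hemisphere == "N") 32600L + utm_zone else 32700L + utm_zone
  central_meridian <- -183L + 6L * utm_zone
  false_northing <- if (hemisphere == "N") 0 else 10000000
  wkt <- paste0(
    'PROJCS["WGS 84 / UTM zone ', utm_zone, hemisphere, '",',
    'GEOGCS["WGS 84",DATUM["WGS_1984",',
    'SPHEROID["WGS 84",6378137,298.257223563]],',
    'PRIMEM["Greenwich",0],UNIT["degree",0.0174532925199433]],',
    'PROJECTION["Transverse_Mercator"],',
    'PARAMETER["latitude_of_origin",0],',
    'PARAMETER["central_meridian",', central_meridian, '],',
    'PARAMETER["scale_factor",0.9996],',
    'PARAMETER["false_easting",500000],',
    'PARAMETER["false_northing",', format(false_northing, scientific = FALSE),
    '],UNIT["metre",1]]')
  list(epsg = epsg, wkt = wkt)
}

# corners of an axis-aligned rect as a closed clockwise ring (5 x 2 matrix)
rect_ring <- function(rect) {
  m <- rbind(c(rect[["xmin"]], rect[["ymin"]]),
             c(rect[["xmin"]], rect[["ymax"]]),
             c(rect[["xmax"]], rect[["ymax"]]),
             c(rect[["xmax"]], rect[["ymin"]]),
             c(rect[["xmin"]], rect[["ymin"]]))
  colnames(m) <- c("x", "y")
  m
}

#' Georeference a local-frame layout
#'
#' Rotates and translates every polygon's full and buffered rings into UTM
#' using the A-B line, and attaches the WGS-84 UTM coordinate reference
#' system when a zone is given (otherwise the set carries no CRS).
#'
#' @param layout list of local polygons from [build_layout()].
#' @param ab an \code{ab_line}.
#' @return a \code{geo_polygon_set}: list with \code{polygons} (each carrying
#'   \code{unique_id}, attributes and closed clockwise \code{full}/
#'   \code{buffer} rings in UTM) and \code{crs} (list(epsg, wkt) or
#'   \code{NULL}), plus \code{theta}, the bearing in radians.
#' @export
georeference <- function(layout, ab) {
  stopifnot(inherits(ab, "ab_line"), length(layout) > 0)
  theta <- bearing(ab)
  polys <- lapply(layout, function(p) {
    fr <- rect_ring(p$full)
    br <- rect_ring(p$buffer)
    list(unique_id = p$unique_id, plot = p$plot, barcode = p$barcode,
         range = p$range, row_first = p$row_first, row_last = p$row_last,
         full = local_to_utm(fr[, 1], fr[, 2], ab, theta),
         buffer = local_to_utm(br[, 1], br[, 2], ab, theta))
  })
  crs <- if (!is.null(ab$utm_zone)) {
    epsg_for_zone(ab$utm_zone, ab$hemisphere)
  } else NULL
  structure(list(polygons = polys, crs = crs, theta = theta),
            class = "geo_polygon_set")
}
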