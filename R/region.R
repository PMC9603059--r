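#' Construct a study region from planar polygon coordinates
#'
#' A study region is a closed polygon (possibly multi-part) in a projected
#' coordinate reference system. Geographic (longitude/latitude) coordinates
#' are rejected: all geometric operations in the package assume planar
#' geometry with a linear unit.
#'
#' @param parts A two-column matrix of `(x, y)` vertices for a single-part
#'   region, or a list of such matrices for a multi-part region. Rings may be
#'   given open or closed (a repeated final vertex is dropped).
#' @param unit Linear unit of the coordinates, `"feet"` or `"meters"`.
#'   `"degrees"` is rejected with an explanatory error: geometric operations
#'   assume planar coordinates, so geographic boundaries must be projected
#'   first.
#' @return An object of class `hex_region`: a list with elements `parts`
#'   (list of CCW open rings) and `unit`.
#' @examples
#' sq <- hex_region(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), unit = "meters")
#' region_area(sq)
#' @export
hex_region <- function(parts, unit = c("feet", "meters", "degrees")) {
  unit <- match.arg(unit)
  if (unit == "degrees") {
    abort(paste(
      "Geographic (lon/lat) coordinates are not supported.",
      "Project the boundary to a planar CRS with a linear unit first."
    ))
  }
  if (is.matrix(parts)) parts <- list(parts)
  if (!is.list(parts) || length(parts) == 0) {
    abort("`parts` must be a coordinate matrix or a non-empty list of them.")
  }
  parts <- lapply(parts, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || !is.numeric(p)) {
      abort("Each region part must be a numeric two-column (x, y) matrix.")
    }
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3) abort("Each region part needs at least 3 distinct vertices.")
    if (!all(is.finite(p))) abort("Region coordinates must be finite.")
    polygon_ccw(p)
  })
  region <- structure(list(parts = parts, unit = unit), class = "hex_region")
  if (region_area(region) <= 0) abort("Region must have strictly positive area.")
  region
}

#' @rdname hex_region
#' @param region A `hex_region`.
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "hex_region"))
  sum(vapply(region$parts, polygon_area, numeric(1)))
}

#' @export
print.hex_region <- function(x, ...) {
  cat("<hex_region> ", length(x$parts), " part(s), area ",
      format(region_area(x), digits = 6), " square ", x$unit, "\n", sep = "")
  invisible(x)
}

region_bbox <- function(region) {
  xy <- do.call(rbind, region$parts)
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

#' Read a study region from a GeoJSON file
#'
#' Reads the first Polygon or MultiPolygon geometry found in a GeoJSON file
#' (Feature, FeatureCollection, or bare geometry). Holes are not supported;
#' only the outer ring of each polygon part is used.
#'
#' @param path Path to a GeoJSON file with planar (projected) coordinates.
#' @param unit Linear unit of the coordinates.
#' @return A [hex_region()].
#' @export
read_region_geojson <- function(path, unit = c("feet", "meters")) {
  gj <- jsonlite::read_json(path)
  geom <- geojson_first_geometry(gj)
  if (is.null(geom)) abort("No Polygon/MultiPolygon geometry found in file.")
  parts <- geojson_polygon_parts(geom)
  hex_region(parts, unit = match.arg(unit))
}

geojson_first_geometry <- function(x) {
  type <- x[["type"]]
  if (is.null(type)) return(NULL)
  switch(type,
    FeatureCollection = {
      for (f in x[["features"]]) {
        g <- geojson_first_geometry(f)
        if (!is.null(g)) return(g)
      }
      NULL
    },
    Feature = geojson_first_geometry(x[["geometry"]]),
    Polygon = x,
    MultiPolygon = x,
    NULL
  )
}

geojson_polygon_parts <- function(geom) {
  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  if (geom[["type"]] == "Polygon") {
    list(ring_to_matrix(geom[["coordinates"]][[1]]))
  } else {
    lapply(geom[["coordinates"]], function(poly) ring_to_matrix(poly[[1]]))
  }
}
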