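# File formats: survey and grid tables as CSV (lossless numeric round-trip),
# polygons as GeoJSON. Coordinates are always (lon, lat), WGS84 degrees.

#' Read a point survey CSV
#'
#' Required columns: `lon`, `lat`, `value`. Optional columns (`site_id`,
#' `crop`, covariates, ...) are passed through. Coordinates are validated;
#' malformed rows are reported with their file line numbers (header = line
#' 1). A `site_id` column is added when absent.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_survey_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("lon", "lat", "value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("Survey CSV is missing required column(s): ",
                 paste(miss, collapse = ", "), "."))
  }
  bad <- !is.finite(x$lon) | !is.finite(x$lat) |
    abs(x$lon) > 180 | abs(x$lat) > 90 | !is.finite(x$value)
  if (any(bad)) {
    lines <- which(bad) + 1L   # header occupies line 1
    abort(paste0("Malformed survey row(s) at file line(s): ",
                 paste(head(lines, 10L), collapse = ", "),
                 " (invalid coordinates or non-finite value)."))
  }
  if (!"site_id" %in% names(x)) {
    x$site_id <- sprintf("S%04d", seq_len(nrow(x)))
  }
  x
}

#' Write a survey or map table to CSV
#'
#' Numeric fields survive a write-then-read round trip losslessly (readr
#' writes shortest-round-trip representations of doubles). List columns
#' (for example kriging weights) are dropped with a message.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(data, path) {
  is_list <- vapply(data, is.list, logical(1))
  if (any(is_list)) {
    message("Dropping list column(s) for CSV export: ",
            paste(names(data)[is_list], collapse = ", "))
    data <- data[!is_list]
  }
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read polygons from a GeoJSON file
#'
#' Accepts `Polygon` and `MultiPolygon` geometries, bare, as `Feature`s or
#' in a `FeatureCollection`. Each polygon is returned as a list of rings
#' (matrices of lon/lat vertices); the first ring is the outer boundary,
#' subsequent rings are holes.
#'
#' @param path Path to a GeoJSON file.
#' @return A list of polygons; each polygon is a list of ring matrices.
#'   Feature properties, when present, are kept in attribute
#'   `"properties"` of each polygon.
#' @export
read_polygons_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  collect <- function(obj, props = NULL) {
    ty <- obj$type %||% abort("GeoJSON object has no 'type'.")
    switch(ty,
      FeatureCollection = purrr::flatten(purrr::map(obj$features, collect)),
      Feature = collect(obj$geometry, props = obj$properties),
      Polygon = list(set_attrs(rings_from_coords(obj$coordinates),
                               properties = props)),
      MultiPolygon = purrr::map(obj$coordinates, function(p)
        set_attrs(rings_from_coords(p), properties = props)),
      abort(paste0("Unsupported GeoJSON geometry type: ", ty)))
  }
  collect(g)
}

rings_from_coords <- function(coords) {
  purrr::map(coords, function(ring) {
    m <- do.call(rbind, purrr::map(ring, function(pt) c(pt[[1]], pt[[2]])))
    validate_lonlat(m)
    m
  })
}

#' Write polygons to a GeoJSON file
#'
#' @param polygons A list of polygons as returned by
#'   [read_polygons_geojson()], or a single ring matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  if (is.matrix(polygons) || is.data.frame(polygons)) polygons <- list(polygons)
  feats <- purrr::map(polygons, function(p) {
    rings <- as_polygon_rings(p)
    coords <- purrr::map(rings, function(r) {
      r <- close_ring(r)
      purrr::map(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature", properties = attr(p, "properties") %||% NULL,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

close_ring <- function(r) {
  if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ]) else r
  r
}

# Normalise a polygon argument to a list of ring matrices.
as_polygon_rings <- function(polygon) {
  if (is.list(polygon) && !is.data.frame(polygon)) {
    rings <- purrr::map(polygon, function(r) as_lonlat_matrix(r))
  } else {
    rings <- list(as_lonlat_matrix(polygon))
  }
  if (any(vapply(rings, nrow, integer(1)) < 3)) {
    abort("Polygon rings need at least 3 vertices.")
  }
  rings
}

#' Test points for polygon membership
#'
#' Even-odd ray-casting rule over all rings, so holes are excluded: a point
#' inside an odd number of rings is inside the polygon.
#'
#' @param pts Data frame with `lon`, `lat` (or two-column matrix).
#' @param polygon A ring matrix or list of rings (outer first, holes after).
#' @return Logical vector, one element per point.
#' @export
point_in_polygon <- function(pts, polygon) {
  m <- as_lonlat_matrix(pts)
  rings <- as_polygon_rings(polygon)
  inside <- rep(FALSE, nrow(m))
  for (ring in rings) inside <- xor(inside, pip_ring(m[, 1], m[, 2], ring))
  inside
}

pip_ring <- function(lon, lat, ring) {
  # drop an explicit closing vertex if present
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  n <- nrow(ring)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
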