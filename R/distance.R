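# Single distance metric used everywhere in the package: great-circle
# distance on a sphere of radius 6,378,137 m (WGS84 equatorial radius),
# computed by geosphere::distVincentySphere.

#' Great-circle distance between points
#'
#' Spherical (great-circle) distance between pairs of (lon, lat) points,
#' using sphere radius 6,378,137 m. This is the single distance metric used
#' by every function in the package (variogram binning, kriging covariances,
#' nearest-neighbour linkage, spatial mixed models).
#'
#' @param p1,p2 A numeric vector `c(lon, lat)`, a two-column matrix, or a
#'   data frame with `lon` and `lat` columns; decimal degrees WGS84.
#' @return Distance(s) in metres.
#' @examples
#' great_circle_distance(c(0, 0), c(0, 1))   # one degree of latitude
#' @export
great_circle_distance <- function(p1, p2) {
  m1 <- as_lonlat_matrix(p1)
  m2 <- as_lonlat_matrix(p2)
  geosphere::distVincentySphere(m1, m2)
}

#' Pairwise great-circle distance matrix in kilometres
#'
#' @param x,y Data frames with `lon`, `lat` columns (or two-column
#'   matrices). `y` defaults to `x`.
#' @return A `nrow(x)` by `nrow(y)` matrix of distances in km.
#' @export
gc_distance_km <- function(x, y = x) {
  geosphere::distm(as_lonlat_matrix(x), as_lonlat_matrix(y),
                   fun = geosphere::distVincentySphere) / 1000
}

as_lonlat_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("lon", "lat") %in% names(x))) {
      abort("Coordinate data frame must have 'lon' and 'lat' columns.")
    }
    m <- cbind(x$lon, x$lat)
  } else if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 2) abort("A coordinate vector must be c(lon, lat).")
    m <- matrix(x, ncol = 2)
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 2) abort("Coordinate matrix must have two columns (lon, lat).")
  }
  storage.mode(m) <- "double"
  validate_lonlat(m)
  m
}

validate_lonlat <- function(m) {
  bad <- !is.finite(m[, 1]) | !is.finite(m[, 2]) |
    abs(m[, 1]) > 180 | abs(m[, 2]) > 90
  if (any(bad)) {
    abort(paste0("Invalid lon/lat at row(s): ",
                 paste(head(which(bad), 10L), collapse = ", "),
                 " (require lon in [-180, 180], lat in [-90, 90])."))
  }
  invisible(m)
}
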