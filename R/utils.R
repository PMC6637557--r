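# Shared geometry and small helpers.

# km per degree of latitude on the 6371-km sphere (2*pi*6371/360 ~ 111.19;
# the simulator and the credible-box conversion use the conventional 111.32).
KM_PER_DEG <- 111.32
EARTH_RADIUS_KM <- 6371

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over all
#' arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (longitude
#'   negative west).
#' @return Distance(s) in km.
#' @examples
#' great_circle_km(0, 0, 0, 1) # ~111.19
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# Pairwise great-circle distance matrix (km) for a set of points.
great_circle_matrix_km <- function(lon, lat) {
  geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) *
    (EARTH_RADIUS_KM / 6378137)
}

# Even-odd (ray casting) point-in-polygon test; points on an edge or vertex
# count as inside. `poly` is a two-column matrix of lon/lat vertices; an
# unclosed ring is closed implicitly.
point_in_polygon <- function(lon, lat, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) {
    px <- px[-n]; py <- py[-n]; n <- n - 1L
  }
  vapply(seq_along(lon), function(k) {
    x <- lon[k]; y <- lat[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
      # on-vertex / on-edge -> inside
      if ((xi == x && yi == y) ||
          (((yi <= y && y <= yj) || (yj <= y && y <= yi)) &&
           ((xi <= x && x <= xj) || (xj <= x && x <= xi)) &&
           abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi)) < 1e-12)) {
        return(TRUE)
      }
      if ((yi > y) != (yj > y)) {
        xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xcross) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# Read a GeoJSON Polygon (first ring) into a two-column lon/lat matrix.
read_polygon_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(gj$type) && identical(gj$type, "FeatureCollection")) {
    gj$features$geometry
  } else if (!is.null(gj$geometry)) gj$geometry else gj
  coords <- geom$coordinates
  while (is.list(coords)) coords <- coords[[1]]
  if (length(dim(coords)) == 3) coords <- coords[1, , ]
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  coords
}

write_polygon_geojson <- function(poly, path) {
  ring <- lapply(seq_len(nrow(poly)), function(i) c(poly[i, 1], poly[i, 2]))
  if (!isTRUE(all.equal(poly[1, ], poly[nrow(poly), ]))) {
    ring <- c(ring, ring[1])
  }
  obj <- list(type = "Polygon", coordinates = list(ring))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
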