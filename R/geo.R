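# Geodesic and small planar-geometry helpers shared across modules.
# All distances in meters unless a suffix says otherwise; coordinates are
# lon/lat degrees on WGS84.

# Authalic earth radius (m), used by the local equal-area projection.
.R_EARTH <- 6371008.8

#' Geodesic distance between points
#'
#' Distance on the WGS84 ellipsoid (default) or by the haversine formula on a
#' sphere. Vectorized over rows.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @param method `"ellipsoid"` (WGS84 geodesic, the default) or `"haversine"`.
#' @return Distance(s) in meters.
#' @export
geo_dist_m <- function(lon1, lat1, lon2, lat2, method = c("ellipsoid", "haversine")) {
  method <- match.arg(method)
  p1 <- cbind(lon1, lat1)
  p2 <- cbind(lon2, lat2)
  if (method == "ellipsoid") {
    geosphere::distGeo(p1, p2)
  } else {
    geosphere::distHaversine(p1, p2)
  }
}

# Local azimuthal equal-area projection centered on (lon0, lat0).
# Returns x/y in meters. Equal-area so that grid-cell areas are faithful at
# the scale of a residency cluster (tens of km).
laea_project <- function(lon, lat, lon0, lat0) {
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- lat0 * pi / 180
  kp2 <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  # Antipodal points are never in play at cluster scale; guard anyway.
  kp2[kp2 < 1e-12] <- 1e-12
  k <- sqrt(2 / kp2)
  x <- .R_EARTH * k * cos(phi) * sin(lam)
  y <- .R_EARTH * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam))
  cbind(x = x, y = y)
}

laea_unproject <- function(x, y, lon0, lat0) {
  rho <- sqrt(x^2 + y^2)
  phi0 <- lat0 * pi / 180
  out <- cbind(lon = rep(lon0, length(x)), lat = rep(lat0, length(x)))
  nz <- rho > 1e-9
  if (any(nz)) {
    c_ang <- 2 * asin(pmin(1, rho[nz] / (2 * .R_EARTH)))
    phi <- asin(cos(c_ang) * sin(phi0) + y[nz] * sin(c_ang) * cos(phi0) / rho[nz])
    lam <- atan2(x[nz] * sin(c_ang),
                 rho[nz] * cos(phi0) * cos(c_ang) - y[nz] * sin(phi0) * sin(c_ang))
    out[nz, "lon"] <- lon0 + lam * 180 / pi
    out[nz, "lat"] <- phi * 180 / pi
  }
  out
}

#' Test points against a polygon (closed convention)
#'
#' Ray-casting point-in-polygon with points on the boundary counted as inside.
#' The closed convention is fixed so season assignment is reproducible.
#'
#' @param lon,lat Point coordinates (degrees), vectorized.
#' @param poly A two-column matrix or data.frame of polygon vertices
#'   (lon, lat); the ring need not be explicitly closed.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  poly <- as.matrix(poly)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  vapply(seq_along(lon), function(i) {
    x <- lon[i]; y <- lat[i]
    # boundary test: point on any edge counts as inside
    dx <- px[j] - px; dy <- py[j] - py
    t <- ifelse(dx^2 + dy^2 > 0, ((x - px) * dx + (y - py) * dy) / (dx^2 + dy^2), 0)
    t <- pmin(1, pmax(0, t))
    d2 <- (px + t * dx - x)^2 + (py + t * dy - y)^2
    if (any(d2 < 1e-18)) return(TRUE)
    inside <- FALSE
    for (k in seq_len(n)) {
      xi <- px[k]; yi <- py[k]; xj <- px[j[k]]; yj <- py[j[k]]
      if ((yi > y) != (yj > y)) {
        xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

# Signed east-west geodesic offset (m) of point lon relative to reference
# lon0, measured along the parallel at latitude lat. Negative = west.
signed_ew_dist_m <- function(lon, lon0, lat) {
  dlon <- ((lon - lon0 + 180) %% 360) - 180
  d <- geosphere::distGeo(cbind(lon0, lat), cbind(lon0 + dlon, lat))
  sign(dlon) * d
}

# Unit 3-vectors for fast nearest-neighbor searches on the sphere.
lonlat_to_xyz <- function(lon, lat) {
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}
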