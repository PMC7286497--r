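# Spherical geometry on the package's single convention: a sphere of radius
# EARTH_RADIUS_M, haversine distances, initial bearings, slerp interpolation.
# All functions are vectorized over coordinates given in decimal degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle distance between points (haversine)
#'
#' Haversine distance on a sphere of radius 6,371,000 m, the single geodesic
#' convention used by every operation in the package (distances, speeds,
#' interpolation, simulation). Vectorized; arguments recycle as usual.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 decimal degrees.
#' @return Distance(s) in meters.
#' @export
#' @examples
#' haversine_m(0, 0, 0, 0.5) / 1000  # equatorial half-degree, ~55.6 km
haversine_m <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

# Initial bearing (radians, clockwise from north, in (-pi, pi]) from point 1
# toward point 2. Undefined (NA) for coincident points.
bearing_rad <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  b <- atan2(y, x)
  b[abs(y) < .Machine$double.eps & abs(x) < .Machine$double.eps] <- NA_real_
  b
}

# Destination point given start, bearing (rad, clockwise from north) and
# distance (m) along the great circle.
destination_point <- function(lat, lon, bearing, dist_m) {
  d <- dist_m / EARTH_RADIUS_M
  p1 <- deg2rad(lat); l1 <- deg2rad(lon)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(bearing))
  l2 <- l1 + atan2(sin(bearing) * sin(d) * cos(p1),
                   cos(d) - sin(p1) * sin(p2))
  list(lat = rad2deg(p2), lon = rad2deg(wrap_angle(l2)))
}

# Spherical linear interpolation between two points at fraction f in [0, 1]
# along the connecting great circle (constant angular speed).
slerp_point <- function(lat1, lon1, lat2, lon2, f) {
  to_xyz <- function(lat, lon) {
    phi <- deg2rad(lat); lam <- deg2rad(lon)
    c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  }
  a <- to_xyz(lat1, lon1); b <- to_xyz(lat2, lon2)
  dotab <- min(1, max(-1, sum(a * b)))
  omega <- acos(dotab)
  if (omega < 1e-12) {
    v <- a
  } else {
    v <- (sin((1 - f) * omega) * a + sin(f * omega) * b) / sin(omega)
    v <- v / sqrt(sum(v^2))
  }
  list(lat = rad2deg(asin(v[3])), lon = rad2deg(atan2(v[2], v[1])))
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta Angle(s) in radians.
#' @return Angle(s) wrapped into `(-pi, pi]`.
#' @export
wrap_angle <- function(theta) {
  out <- -((-theta + pi) %% (2 * pi) - pi)
  out
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Tiny polynomial rolling hash of a character scalar, for config fingerprints
# in run manifests (no digest dependency; exact in double precision).
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
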