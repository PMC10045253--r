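# Spherical and local planar geometry helpers.
#
# Polygons are represented as plain numeric matrices with columns lon, lat
# (degrees, WGS84); rings need not be closed (first vertex is not repeated).
# A multipolygon is a list of such rings (holes are not supported: site
# polygons are solid habitat patches).

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km.
#' Vectorised over coordinates.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0)   # one degree of latitude, ~111.195 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90))
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Lambert azimuthal equal-area projection about (lon0, lat0); returns metres.
# Used for area-true centroids and metric buffering of site polygons.
laea_project <- function(lon, lat, lon0, lat0) {
  R <- EARTH_RADIUS_KM * 1000
  l <- lon * pi / 180; p <- lat * pi / 180
  l0 <- lon0 * pi / 180; p0 <- lat0 * pi / 180
  denom <- 1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(l - l0)
  k <- sqrt(2 / pmax(denom, 1e-12))
  cbind(
    x = R * k * cos(p) * sin(l - l0),
    y = R * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(l - l0))
  )
}

laea_unproject <- function(x, y, lon0, lat0) {
  R <- EARTH_RADIUS_KM * 1000
  l0 <- lon0 * pi / 180; p0 <- lat0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * R)))
  lat <- ifelse(rho < 1e-9, lat0,
    asin(cos(c_ang) * sin(p0) + y * sin(c_ang) * cos(p0) / pmax(rho, 1e-12)) * 180 / pi)
  lon <- ifelse(rho < 1e-9, lon0,
    (l0 + atan2(x * sin(c_ang),
                rho * cos(p0) * cos(c_ang) - y * sin(p0) * sin(c_ang))) * 180 / pi)
  cbind(lon = lon, lat = lat)
}

# Shoelace area (signed, in the units of the coordinates^2).
ring_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Area-weighted centroid of a planar ring.
ring_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Area-weighted centroid of a lon/lat multipolygon, computed in a local
# equal-area projection about the bounding-box centre; returns c(lon, lat).
multipolygon_centroid <- function(rings) {
  all_xy <- do.call(rbind, rings)
  lon0 <- mean(range(all_xy[, 1])); lat0 <- mean(range(all_xy[, 2]))
  cx <- 0; cy <- 0; atot <- 0
  for (r in rings) {
    pr <- laea_project(r[, 1], r[, 2], lon0, lat0)
    a <- abs(ring_area_signed(pr))
    cc <- ring_centroid(pr)
    cx <- cx + a * cc[1]; cy <- cy + a * cc[2]; atot <- atot + a
  }
  if (atot < 1e-9) {
    ll <- c(mean(all_xy[, 1]), mean(all_xy[, 2]))
    return(c(lon = ll[1], lat = ll[2]))
  }
  ll <- laea_unproject(cx / atot, cy / atot, lon0, lat0)
  c(lon = ll[1, 1], lat = ll[1, 2])
}

# Area of a lon/lat multipolygon in km^2 (local equal-area projection).
multipolygon_area_km2 <- function(rings) {
  all_xy <- do.call(rbind, rings)
  lon0 <- mean(range(all_xy[, 1])); lat0 <- mean(range(all_xy[, 2]))
  sum(vapply(rings, function(r) {
    pr <- laea_project(r[, 1], r[, 2], lon0, lat0)
    abs(ring_area_signed(pr)) / 1e6
  }, numeric(1)))
}

# Ray-casting point-in-ring test on lon/lat coordinates; points exactly on an
# edge or vertex count as inside.
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  rx <- ring[, 1]; ry <- ring[, 2]
  inside <- logical(length(lon))
  on_edge <- logical(length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- rx[i]; yi <- ry[i]; xj <- rx[j]; yj <- ry[j]
    # boundary check: point within the segment's bbox and collinear
    dx <- xj - xi; dy <- yj - yi
    cross <- dx * (lat - yi) - dy * (lon - xi)
    seg <- abs(cross) < 1e-12 &
      lon >= pmin(xi, xj) - 1e-12 & lon <= pmax(xi, xj) + 1e-12 &
      lat >= pmin(yi, yj) - 1e-12 & lat <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | seg
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

point_in_multipolygon <- function(lon, lat, rings) {
  hit <- logical(length(lon))
  for (r in rings) {
    todo <- !hit
    if (!any(todo)) break
    hit[todo] <- point_in_ring(lon[todo], lat[todo], r)
  }
  hit
}

# Resample a ring's perimeter so consecutive sample points are at most
# `step_m` apart (used for boundary-to-boundary distances when merging sites).
sample_perimeter <- function(ring, step_m = 100) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(ring))) {
    a <- closed[i, ]; b <- closed[i + 1, ]
    d_m <- haversine_km(a[1], a[2], b[1], b[2]) * 1000
    k <- max(1L, ceiling(d_m / step_m))
    t <- (seq_len(k) - 1) / k
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

# Minimum boundary-to-boundary great-circle distance (km) between two
# multipolygons, approximated by perimeter sampling.
min_boundary_distance_km <- function(rings_a, rings_b, step_m = 100) {
  pa <- do.call(rbind, lapply(rings_a, sample_perimeter, step_m = step_m))
  pb <- do.call(rbind, lapply(rings_b, sample_perimeter, step_m = step_m))
  # distHaversine is vectorised pairwise; expand the smaller set
  best <- Inf
  for (i in seq_len(nrow(pa))) {
    d <- haversine_km(pa[i, 1], pa[i, 2], pb[, 1], pb[, 2])
    m <- min(d)
    if (m < best) best <- m
    if (best == 0) break
  }
  best
}

# Outward offset (Minkowski sum with a disk) of a convex planar ring.
# Each edge is translated outward by `r`; circular arcs (discretised with
# `arc_steps` segments per corner) join the offset edges. The ring must be
# convex; reflex corners are joined by a straight miter instead of an arc,
# which under-buffers locally (documented limitation).
offset_ring_planar <- function(xy, r, arc_steps = 16) {
  if (r == 0) return(xy)
  n <- nrow(xy)
  # ensure counter-clockwise orientation
  if (ring_area_signed(xy) < 0) xy <- xy[n:1, , drop = FALSE]
  nxt <- c(2:n, 1)
  ex <- xy[nxt, 1] - xy[, 1]
  ey <- xy[nxt, 2] - xy[, 2]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 1e-9
  xy <- xy[keep, , drop = FALSE]
  n <- nrow(xy); nxt <- c(2:n, 1)
  ex <- xy[nxt, 1] - xy[, 1]; ey <- xy[nxt, 2] - xy[, 2]
  len <- sqrt(ex^2 + ey^2)
  # outward normal of a CCW ring edge is (ey, -ex)/len
  nx <- ey / len; ny <- -ex / len
  out <- list()
  prev <- c(n, 1:(n - 1))
  for (i in seq_len(n)) {
    # arc at vertex i from previous edge normal to current edge normal
    a0 <- atan2(ny[prev[i]], nx[prev[i]])
    a1 <- atan2(ny[i], nx[i])
    # turn angle wrapped to (-pi, pi]; positive = convex corner of a CCW ring
    sweep <- (a1 - a0 + pi) %% (2 * pi) - pi
    if (sweep < 1e-9) {
      # straight or reflex vertex: single offset point (miter join)
      out[[length(out) + 1]] <- cbind(xy[i, 1] + r * nx[i], xy[i, 2] + r * ny[i])
    } else {
      ang <- a0 + sweep * (0:arc_steps) / arc_steps
      out[[length(out) + 1]] <- cbind(xy[i, 1] + r * cos(ang), xy[i, 2] + r * sin(ang))
    }
    # offset edge endpoints
    out[[length(out) + 1]] <- cbind(
      c(xy[i, 1] + r * nx[i], xy[nxt[i], 1] + r * nx[i]),
      c(xy[i, 2] + r * ny[i], xy[nxt[i], 2] + r * ny[i]))
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("x", "y")
  res
}
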