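# Planar/geodesic helpers shared across modules. All coordinates are
# (lon, lat) in WGS84. Distances between point pairs go through geosphere;
# the small polygon primitives below work in a local equirectangular frame,
# which is accurate for the near-equatorial extents this package targets.

# metres per degree of latitude (WGS84 mean); longitude is scaled by cos(lat)
.M_PER_DEG <- 111319.49

#' @keywords internal
deg_per_m <- function(lat = 0) {
  c(lon = 1 / (.M_PER_DEG * max(cos(lat * pi / 180), 1e-6)),
    lat = 1 / .M_PER_DEG)
}

#' Geodesic length of a polyline in kilometres
#'
#' @param mat two-column matrix of (lon, lat) vertices.
#' @return length in km.
#' @keywords internal
polyline_length_km <- function(mat) {
  if (nrow(mat) < 2) return(0)
  sum(geosphere::distGeo(mat[-nrow(mat), , drop = FALSE],
                         mat[-1, , drop = FALSE])) / 1000
}

# distance in metres from each point in `pts` (n x 2) to a single point `p`
.dist_to_point_m <- function(pts, p) {
  geosphere::distGeo(pts, matrix(p, ncol = 2)[rep(1, nrow(pts)), , drop = FALSE])
}

#' Cluster coordinates onto a tolerance grid
#'
#' Order-independent grid-hash clustering: coordinates are rounded to a grid
#' whose cell size equals the tolerance, and all points falling in the same
#' cell become one cluster. Cluster coordinates are the member means, and
#' cluster ids are assigned in lexicographic (lon, lat) order so the result
#' is deterministic and independent of input order.
#'
#' @param coords two-column matrix of (lon, lat).
#' @param tolerance_m merge tolerance in metres.
#' @return list with `assignment` (integer cluster id per input row) and
#'   `centers` (matrix of cluster lon/lat, row i = cluster i).
#' @keywords internal
grid_cluster <- function(coords, tolerance_m = 1) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  cell <- tolerance_m * deg_per_m(mean(coords[, 2]))["lat"]
  key <- paste(round(coords[, 1] / cell), round(coords[, 2] / cell))
  centers_lon <- tapply(coords[, 1], key, mean)
  centers_lat <- tapply(coords[, 2], key, mean)
  keys <- names(centers_lon)
  ord <- order(centers_lon[keys], centers_lat[keys])
  keys <- keys[ord]
  assignment <- match(key, keys)
  list(assignment = assignment,
       centers = cbind(lon = unname(centers_lon[keys]),
                       lat = unname(centers_lat[keys])))
}

#' Clip a polyline to a leading fraction of its length
#'
#' Returns the sub-polyline covering `fraction` of the total arc length,
#' measured from the first vertex (set `from_end = TRUE` to measure from the
#' last vertex instead).
#'
#' @keywords internal
clip_polyline <- function(mat, fraction, from_end = FALSE) {
  stopifnot(nrow(mat) >= 2, fraction >= 0, fraction <= 1)
  if (from_end) mat <- mat[nrow(mat):1, , drop = FALSE]
  if (fraction >= 1) {
    out <- mat
  } else {
    seg_len <- geosphere::distGeo(mat[-nrow(mat), , drop = FALSE],
                                  mat[-1, , drop = FALSE])
    target <- fraction * sum(seg_len)
    cum <- cumsum(seg_len)
    k <- which(cum >= target - 1e-9)[1]
    prev <- if (k == 1) 0 else cum[k - 1]
    f <- if (seg_len[k] <= 0) 0 else (target - prev) / seg_len[k]
    cut_pt <- mat[k, ] + f * (mat[k + 1, ] - mat[k, ])
    out <- rbind(mat[seq_len(k), , drop = FALSE], cut_pt)
  }
  if (from_end) out <- out[nrow(out):1, , drop = FALSE]
  unname(out)
}

#' Constant-width buffer around a polyline
#'
#' Builds one closed polygon ring per two-vertex leg (a rectangle capped by
#' circular arcs at both ends), in a local equirectangular frame centred on
#' the polyline. The catchment polygon is the undissolved union of these
#' rings; overlaps between rings are harmless for coverage/containment use.
#'
#' @param mat polyline vertex matrix (lon, lat).
#' @param width_m buffer half-width in metres.
#' @param n_cap number of points per semicircular cap.
#' @return list of closed rings, each a two-column (lon, lat) matrix.
#' @keywords internal
buffer_polyline <- function(mat, width_m = 250, n_cap = 8) {
  stopifnot(nrow(mat) >= 1, width_m > 0)
  scale <- deg_per_m(mean(mat[, 2]))
  if (nrow(mat) == 1) mat <- rbind(mat, mat)
  rings <- vector("list", nrow(mat) - 1)
  for (i in seq_len(nrow(mat) - 1)) {
    a <- mat[i, ]
    b <- mat[i + 1, ]
    # work in metres relative to a
    d <- c((b[1] - a[1]) / scale["lon"], (b[2] - a[2]) / scale["lat"])
    len <- sqrt(sum(d^2))
    ang <- if (len < 1e-9) 0 else atan2(d[2], d[1])
    th1 <- ang + pi / 2 + seq(0, pi, length.out = n_cap + 1)  # cap at a
    th2 <- ang - pi / 2 + seq(0, pi, length.out = n_cap + 1)  # cap at b
    cap_a <- cbind(cos(th1), sin(th1)) * width_m
    cap_b <- cbind(cos(th2), sin(th2)) * width_m +
      matrix(c(len * cos(ang), len * sin(ang)), n_cap + 1, 2, byrow = TRUE)
    ring_m <- rbind(cap_a, cap_b)
    ring_m <- rbind(ring_m, ring_m[1, ])
    rings[[i]] <- cbind(lon = a[1] + ring_m[, 1] * scale["lon"],
                        lat = a[2] + ring_m[, 2] * scale["lat"])
  }
  rings
}

#' Point-in-polygon test (ray casting)
#'
#' @param pts two-column matrix of query points (lon, lat).
#' @param ring closed or open polygon ring as a two-column matrix.
#' @return logical vector, TRUE when the point lies inside the ring.
#' @keywords internal
point_in_ring <- function(pts, ring) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1 }
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Point membership in a multipolygon (list of rings)
#' @keywords internal
point_in_rings <- function(pts, rings) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  inside <- rep(FALSE, nrow(pts))
  for (ring in rings) inside <- inside | point_in_ring(pts, ring)
  inside
}
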