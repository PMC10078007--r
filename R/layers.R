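# Layer containers: plain data.frames with a list-column `geometry` holding
# one (lon, lat) vertex matrix per feature, validated on construction.
# Rivers follow the HydroSHEDS/HydroRIVERS convention: polylines digitized
# upstream -> downstream, linked by a next-downstream segment id (0 = outlet).

#' Construct and validate a river segment layer
#'
#' @param seg_id integer vector of unique, positive segment ids.
#' @param next_down integer vector; id of the next segment downstream,
#'   0 for an outlet segment.
#' @param geometry list of two-column (lon, lat) matrices, each with at least
#'   two vertices, digitized upstream to downstream.
#' @param length_km segment lengths in km (> 0). When `NULL`, computed
#'   geodesically from the geometry.
#' @param discharge_avg average discharge in m3/s (>= 0).
#' @param flow_regime_class seasonal flow-regime variability, one of
#'   `"low"`, `"medium"`, `"high"`.
#' @param stream_speed_class small-integer stream-velocity class (GloRiC
#'   style), used to look up water speed in a [stream_speed_table()].
#' @return a `river_layer` data.frame.
#' @export
river_layer <- function(seg_id, next_down, geometry, length_km = NULL,
                        discharge_avg = 0, flow_regime_class = "medium",
                        stream_speed_class = 1L) {
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    colnames(g) <- c("lon", "lat")
    unname(g)
  })
  if (is.null(length_km)) {
    length_km <- vapply(geometry, polyline_length_km, numeric(1))
  }
  x <- data.frame(seg_id = as.integer(seg_id),
                  next_down = as.integer(next_down),
                  length_km = as.numeric(length_km),
                  discharge_avg = as.numeric(discharge_avg),
                  flow_regime_class = as.character(flow_regime_class),
                  stream_speed_class = as.integer(stream_speed_class))
  x$geometry <- geometry
  class(x) <- c("river_layer", "data.frame")
  validate_river_layer(x)
}

#' Validate a river segment layer
#'
#' Checks every layer invariant: unique positive ids, resolvable downstream
#' links, acyclic downstream relation, well-formed geometry, positive
#' lengths and non-negative discharge. Violations raise an error naming the
#' offending segment id(s); nothing is silently coerced.
#'
#' @param x a `river_layer`.
#' @return `x`, invisibly unchanged, when valid.
#' @export
validate_river_layer <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("seg_id", "next_down", "length_km", "discharge_avg",
            "flow_regime_class", "stream_speed_class", "geometry")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("river layer is missing field(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$seg_id))
    stop("duplicate seg_id: ",
         paste(unique(x$seg_id[duplicated(x$seg_id)]), collapse = ", "))
  if (any(x$seg_id <= 0)) stop("seg_id must be positive")
  if (any(x$next_down == x$seg_id))
    stop("segment points next_down at itself: ",
         paste(x$seg_id[x$next_down == x$seg_id], collapse = ", "))
  dangling <- x$next_down != 0 & !(x$next_down %in% x$seg_id)
  if (any(dangling))
    stop("dangling next_down reference: segment(s) ",
         paste(x$seg_id[dangling], collapse = ", "),
         " point to nonexistent id(s) ",
         paste(unique(x$next_down[dangling]), collapse = ", "))
  bad_geom <- vapply(x$geometry, function(g) {
    !is.matrix(g) || nrow(g) < 2 || ncol(g) != 2 ||
      any(!is.finite(g)) || any(abs(g[, 1]) > 180) || any(abs(g[, 2]) > 90)
  }, logical(1))
  if (any(bad_geom))
    stop("invalid geometry (need >= 2 finite vertices in lon/lat range) for seg_id: ",
         paste(x$seg_id[bad_geom], collapse = ", "))
  if (any(!is.finite(x$length_km) | x$length_km <= 0))
    stop("length_km must be > 0 for seg_id: ",
         paste(x$seg_id[!is.finite(x$length_km) | x$length_km <= 0],
               collapse = ", "))
  if (any(!is.finite(x$discharge_avg) | x$discharge_avg < 0))
    stop("discharge_avg must be >= 0 for seg_id: ",
         paste(x$seg_id[!is.finite(x$discharge_avg) | x$discharge_avg < 0],
               collapse = ", "))
  cyc <- downstream_cycles(x$seg_id, x$next_down)
  if (length(cyc))
    stop("cycle in downstream linkage involving seg_id: ",
         paste(cyc[[1]], collapse = " -> "))
  invisible(x)
}

# Detect cycles in the functional next_down graph. Returns a list of cycles
# (integer vectors of seg ids); empty list when the relation is a forest.
#' @keywords internal
downstream_cycles <- function(seg_id, next_down) {
  nxt <- match(next_down, seg_id)  # NA for outlets / dangling
  state <- integer(length(seg_id)) # 0 unseen, 1 in progress, 2 done
  cycles <- list()
  for (s in seq_along(seg_id)) {
    if (state[s] != 0) next
    path <- integer(0)
    v <- s
    while (!is.na(v) && state[v] == 0) {
      state[v] <- 1L
      path <- c(path, v)
      v <- nxt[v]
    }
    if (!is.na(v) && state[v] == 1L) {
      k <- which(path == v)
      cycles[[length(cycles) + 1]] <- seg_id[path[k:length(path)]]
    }
    state[path] <- 2L
  }
  cycles
}

#' @export
print.river_layer <- function(x, ...) {
  cat("<river_layer> ", nrow(x), " segments, ",
      sum(x$next_down == 0), " outlet(s), total ",
      round(sum(x$length_km), 1), " km\n", sep = "")
  invisible(x)
}

#' Construct and validate a road edge layer
#'
#' Roads follow the GeoFabrik routable-shapefile convention. The `oneway`
#' field accepts both the GeoFabrik dialect (`"B"`, `"F"`, `"T"`) and raw
#' OSM values (`"no"`, `"yes"`, `"-1"`, `""`), normalized on construction to
#' `"B"` (both directions), `"F"` (forward only, in digitization order) or
#' `"T"` (reverse only).
#'
#' @param osm_id character edge ids.
#' @param fclass OSM highway/ferry class.
#' @param geometry list of (lon, lat) vertex matrices.
#' @param oneway direction restriction; see Details.
#' @param maxspeed_kmh numeric speed limit; 0 means unknown.
#' @param length_km edge length in km; computed from geometry when `NULL`.
#' @param name optional street name.
#' @return a `road_layer` data.frame.
#' @export
road_layer <- function(osm_id, fclass = "unclassified", geometry,
                       oneway = "B", maxspeed_kmh = 0, length_km = NULL,
                       name = "") {
  geometry <- lapply(geometry, function(g) unname(as.matrix(g)))
  if (is.null(length_km))
    length_km <- vapply(geometry, polyline_length_km, numeric(1))
  x <- data.frame(osm_id = as.character(osm_id),
                  fclass = as.character(fclass),
                  name = as.character(name),
                  oneway = decode_oneway(oneway),
                  maxspeed_kmh = as.numeric(maxspeed_kmh),
                  length_km = as.numeric(length_km))
  x$geometry <- geometry
  class(x) <- c("road_layer", "data.frame")
  validate_road_layer(x)
}

#' Normalize a oneway encoding
#'
#' @param x character vector in GeoFabrik (`B`/`F`/`T`) or raw OSM
#'   (`no`/`yes`/`1`/`-1`/`""`) dialect.
#' @return character vector over `"B"`, `"F"`, `"T"`.
#' @export
decode_oneway <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("B", "b", "no", "false", "0", "")] <- "B"
  out[x %in% c("F", "f", "yes", "true", "1")] <- "F"
  out[x %in% c("T", "t", "-1", "reverse")] <- "T"
  if (anyNA(out))
    stop("unrecognized oneway value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Validate a road edge layer
#' @param x a `road_layer`.
#' @return `x` invisibly when valid.
#' @export
validate_road_layer <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("osm_id", "fclass", "oneway", "maxspeed_kmh", "length_km",
            "geometry")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("road layer is missing field(s): ", paste(miss, collapse = ", "))
  bad_geom <- vapply(x$geometry, function(g) {
    !is.matrix(g) || nrow(g) < 2 || any(!is.finite(g)) ||
      any(abs(g[, 1]) > 180) || any(abs(g[, 2]) > 90)
  }, logical(1))
  if (any(bad_geom))
    stop("invalid geometry for osm_id: ",
         paste(x$osm_id[bad_geom], collapse = ", "))
  if (!all(x$oneway %in% c("B", "F", "T")))
    stop("oneway must be normalized to B/F/T")
  if (any(x$maxspeed_kmh < 0)) stop("maxspeed_kmh must be >= 0")
  if (any(x$length_km <= 0))
    stop("length_km must be > 0 for osm_id: ",
         paste(x$osm_id[x$length_km <= 0], collapse = ", "))
  invisible(x)
}

#' @export
print.road_layer <- function(x, ...) {
  cat("<road_layer> ", nrow(x), " edges, total ",
      round(sum(x$length_km), 1), " km\n", sep = "")
  invisible(x)
}

#' Construct and validate a facility point layer
#'
#' @param facility_id unique character ids.
#' @param lon,lat WGS84 coordinates.
#' @return a `facility_layer` data.frame.
#' @export
facility_layer <- function(facility_id, lon, lat) {
  x <- data.frame(facility_id = as.character(facility_id),
                  lon = as.numeric(lon), lat = as.numeric(lat))
  if (anyDuplicated(x$facility_id))
    stop("duplicate facility_id: ",
         paste(unique(x$facility_id[duplicated(x$facility_id)]),
               collapse = ", "))
  ok <- is.finite(x$lon) & is.finite(x$lat) &
    abs(x$lon) <= 180 & abs(x$lat) <= 90
  if (!all(ok))
    stop("invalid coordinates for facility_id: ",
         paste(x$facility_id[!ok], collapse = ", "))
  class(x) <- c("facility_layer", "data.frame")
  x
}
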