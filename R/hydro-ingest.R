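# Layer I/O. Geometry layers travel as GeoJSON FeatureCollections, facility
# points as CSV. The routable attribute table is emitted under DBF-legal
# (<= 10 character) field names so the schema drops unchanged into an ESRI
# shapefile attribute table; the name map is fixed in routable_field_names().
# Coordinates and floats are written with 6 decimal places (sub-metre
# precision), which is the documented round-trip tolerance.

.COORD_DIGITS <- 6

# ---- generic GeoJSON plumbing ----------------------------------------------

write_geojson <- function(geometry, properties, path, type = "LineString") {
  stopifnot(length(geometry) == nrow(properties) || nrow(properties) == 0)
  feats <- lapply(seq_along(geometry), function(i) {
    coords <- round(geometry[[i]], .COORD_DIGITS)
    props <- lapply(properties[i, , drop = FALSE], function(v) {
      if (is.numeric(v)) round(unname(v), .COORD_DIGITS) else unname(v)
    })
    list(type = "Feature",
         properties = props,
         geometry = list(type = type,
                         coordinates = lapply(seq_len(nrow(coords)),
                                              function(k) coords[k, ])))
  })
  fc <- list(type = "FeatureCollection",
             properties = list(schema = as.list(names(properties))),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null")
  invisible(path)
}

read_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- fc$features
  geometry <- lapply(feats, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    unname(m)
  })
  # collect the union of property names, preserving schema order when stored
  pnames <- unique(unlist(lapply(feats, function(f) names(f$properties))))
  if (!is.null(fc$properties$schema))
    pnames <- unlist(fc$properties$schema)
  props <- as.data.frame(
    lapply(stats::setNames(pnames, pnames), function(nm) {
      vals <- lapply(feats, function(f) f$properties[[nm]])
      vals <- lapply(vals, function(v) if (is.null(v)) NA else v)
      unlist(vals)
    }), stringsAsFactors = FALSE, optional = TRUE)
  list(geometry = geometry, properties = props)
}

# ---- field maps -------------------------------------------------------------

#' Default attribute-name mapping for river layers
#'
#' Maps the package's canonical river fields to the property names used in a
#' source file. Override entries to ingest HydroSHEDS/HydroRIVERS exports,
#' e.g. `river_field_map(seg_id = "HYRIV_ID", next_down = "NEXT_DOWN")`.
#'
#' @param ... named overrides, `canonical = "file_field"`.
#' @return named character vector.
#' @export
river_field_map <- function(...) {
  map <- c(seg_id = "seg_id", next_down = "next_down",
           length_km = "length_km", discharge_avg = "discharge_avg",
           flow_regime_class = "flow_regime_class",
           stream_speed_class = "stream_speed_class")
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(map))
    if (length(unknown))
      stop("unknown river field(s) in map: ", paste(unknown, collapse = ", "))
    map[names(over)] <- over
  }
  map
}

# ---- river layer ------------------------------------------------------------

#' Read a river segment layer from GeoJSON
#'
#' @param path GeoJSON file of LineString features.
#' @param field_map attribute-name mapping from [river_field_map()].
#' @return validated [river_layer()].
#' @export
read_river_layer <- function(path, field_map = river_field_map()) {
  gj <- read_geojson(path)
  miss <- setdiff(unname(field_map), names(gj$properties))
  if (length(miss) && nrow(gj$properties) > 0)
    stop("mapped field(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))
  p <- gj$properties
  if (nrow(p) == 0) {
    return(river_layer(integer(0), integer(0), list()))
  }
  river_layer(seg_id = p[[field_map["seg_id"]]],
              next_down = p[[field_map["next_down"]]],
              geometry = gj$geometry,
              length_km = p[[field_map["length_km"]]],
              discharge_avg = p[[field_map["discharge_avg"]]],
              flow_regime_class = p[[field_map["flow_regime_class"]]],
              stream_speed_class = p[[field_map["stream_speed_class"]]])
}

#' Write a river segment layer to GeoJSON
#' @param rivers a `river_layer`.
#' @param path output path.
#' @export
write_river_layer <- function(rivers, path) {
  validate_river_layer(rivers)
  props <- as.data.frame(rivers)[, c("seg_id", "next_down", "length_km",
                                     "discharge_avg", "flow_regime_class",
                                     "stream_speed_class")]
  write_geojson(rivers$geometry, props, path)
}

# ---- road layer -------------------------------------------------------------

#' Read a road edge layer from GeoJSON
#'
#' Accepts GeoFabrik-style properties (`osm_id`, `fclass`, `name`, `oneway`,
#' `maxspeed`); the `oneway` dialect is normalized via [decode_oneway()].
#'
#' @param path GeoJSON file of LineString features.
#' @return validated [road_layer()].
#' @export
read_roads_layer <- function(path) {
  gj <- read_geojson(path)
  p <- gj$properties
  if (nrow(p) == 0)
    return(road_layer(character(0), geometry = list()))
  need <- c("osm_id", "fclass", "oneway", "maxspeed")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("road field(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))
  road_layer(osm_id = p$osm_id, fclass = p$fclass,
             name = if (is.null(p$name)) "" else p$name,
             geometry = gj$geometry, oneway = p$oneway,
             maxspeed_kmh = p$maxspeed,
             length_km = if (is.null(p$length_km)) NULL else p$length_km)
}

#' Write a road edge layer to GeoJSON
#' @param roads a `road_layer`.
#' @param path output path.
#' @export
write_roads_layer <- function(roads, path) {
  validate_road_layer(roads)
  props <- as.data.frame(roads)[, c("osm_id", "fclass", "name", "oneway",
                                    "length_km")]
  props$maxspeed <- roads$maxspeed_kmh
  write_geojson(roads$geometry, props, path)
}

# ---- facilities -------------------------------------------------------------

#' Read a facility point layer from CSV
#'
#' Expects columns `facility_id`, `lon`, `lat`.
#'
#' @param path CSV path.
#' @return a `facility_layer`.
#' @export
read_facilities <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("facility_id", "lon", "lat"), names(x))
  if (length(miss))
    stop("facility field(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))
  facility_layer(x$facility_id, x$lon, x$lat)
}

#' Write a facility point layer to CSV
#' @param facilities a `facility_layer`.
#' @param path output path.
#' @export
write_facilities <- function(facilities, path) {
  utils::write.csv(
    as.data.frame(facilities)[, c("facility_id", "lon", "lat")],
    path, row.names = FALSE)
  invisible(path)
}

# ---- routable records -------------------------------------------------------

#' DBF-legal field-name map for the routable layer
#'
#' Fixed mapping from canonical routable-record fields to names of at most
#' 10 characters, so the attribute table is valid as a shapefile DBF. The
#' map is stable across versions; changing it would break round-trips.
#'
#' @return named character vector, `canonical = "dbf_name"`.
#' @export
routable_field_names <- function() {
  c(seg_id = "seg_id", fclass = "fclass",
    from_node = "from_node", to_node = "to_node",
    from_lon = "from_lon", from_lat = "from_lat",
    to_lon = "to_lon", to_lat = "to_lat",
    length_km = "length_km", oneway = "oneway",
    maxspeed_kmh = "maxspeed", avgspeed_kmh = "avgspeed",
    stream_speed_kmh = "stream_kmh",
    tt_down_h = "tt_down_h", tt_up_h = "tt_up_h",
    flow_regime_class = "flow_reg", discharge_avg = "discharge",
    navigable = "navigable", foot_access = "foot",
    width_limit = "width_lim", weight_limit = "weight_lim",
    height_limit = "height_lim",
    bridge = "bridge", tunnel = "tunnel", lanes = "lanes",
    electricity = "electric")
}

#' Write OSM-schema routable records to GeoJSON
#'
#' Attribute names in the output are the DBF-legal names from
#' [routable_field_names()]; a name collision after truncation is an error.
#'
#' @param records a `routable_records` table from [to_osm_records()].
#' @param path output path.
#' @export
write_routable_layer <- function(records, path) {
  map <- routable_field_names()
  if (anyDuplicated(unname(map)))
    stop("field-name collision in DBF name map")
  if (any(nchar(map) > 10))
    stop("DBF field name longer than 10 characters")
  props <- as.data.frame(records)[, names(map), drop = FALSE]
  names(props) <- unname(map)
  write_geojson(records$geometry, props, path)
}

#' Read a routable layer written by [write_routable_layer()]
#' @param path GeoJSON path.
#' @return a `routable_records` data.frame with canonical field names.
#' @export
read_routable_layer <- function(path) {
  gj <- read_geojson(path)
  map <- routable_field_names()
  p <- gj$properties
  if (nrow(p) > 0) {
    miss <- setdiff(unname(map), names(p))
    if (length(miss))
      stop("routable field(s) missing from ", path, ": ",
           paste(miss, collapse = ", "))
    p <- p[, unname(map), drop = FALSE]
  } else {
    p <- as.data.frame(stats::setNames(
      replicate(length(map), logical(0), simplify = FALSE), unname(map)))
  }
  names(p) <- names(map)
  for (nm in c("navigable", "foot_access")) p[[nm]] <- as.logical(p[[nm]])
  p$geometry <- gj$geometry
  class(p) <- c("routable_records", "data.frame")
  p
}
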