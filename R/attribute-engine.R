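# Transport attributes for river segments. A single boat profile supplies
# the cruising and maximum speeds (defaults 18.52 and 37 km/h, the standard
# Amazon riverboat figures); the effective speed over a segment is the boat
# speed plus the water stream speed travelling downstream and minus it
# travelling upstream, floored so upstream travel never stalls the graph.
# Records are emitted in the GeoFabrik-OSM routable schema with the fields
# that are meaningless for rivers (bridge, tunnel, lanes, electricity) held
# at the "do not apply" sentinel and vessel size limits unrestricted.

#' Sentinels used in routable records
#' @name sentinels
#' @keywords internal
DO_NOT_APPLY <- "do not apply"
UNRESTRICTED <- "unrestricted"

#' Boat speed profile
#'
#' @param avg_speed_kmh cruising speed of a standard motorized riverboat in
#'   km/h (default 18.52).
#' @param max_speed_kmh maximum boat speed in km/h (default 37).
#' @param min_effective_speed_kmh floor for the upstream effective speed in
#'   km/h (default 1), so strong streams slow travel rather than silently
#'   disconnecting the network.
#' @return a `boat_profile` list.
#' @export
boat_profile <- function(avg_speed_kmh = 18.52, max_speed_kmh = 37,
                         min_effective_speed_kmh = 1) {
  if (!(min_effective_speed_kmh > 0 &&
        min_effective_speed_kmh <= avg_speed_kmh &&
        avg_speed_kmh <= max_speed_kmh))
    stop("need 0 < min_effective_speed_kmh <= avg_speed_kmh <= max_speed_kmh")
  structure(list(avg_speed_kmh = avg_speed_kmh,
                 max_speed_kmh = max_speed_kmh,
                 min_effective_speed_kmh = min_effective_speed_kmh),
            class = "boat_profile")
}

#' Stream-speed lookup table
#'
#' Maps the small-integer stream-velocity class carried by the river layer
#' to a water speed in km/h. Values must be non-negative and non-decreasing
#' in the class index. The defaults are a modelling choice (slow 0.5,
#' moderate 1.5, fast 3 km/h) and are fully overridable.
#'
#' @param speeds named numeric vector, names are class indices.
#' @return a `stream_speed_table`.
#' @export
stream_speed_table <- function(speeds = c("1" = 0.5, "2" = 1.5, "3" = 3.0)) {
  speeds <- unlist(speeds)
  if (any(speeds < 0)) stop("stream speeds must be >= 0")
  ord <- order(as.integer(names(speeds)))
  if (is.unsorted(speeds[ord]))
    stop("stream speeds must be non-decreasing in class index")
  structure(speeds, class = "stream_speed_table")
}

#' Look up the water speed for stream classes
#' @param table a [stream_speed_table()].
#' @param class integer vector of stream-speed classes.
#' @return numeric km/h.
#' @export
stream_speed_for_class <- function(table, class) {
  out <- unclass(table)[as.character(class)]
  if (anyNA(out))
    stop("unmapped stream speed class: ",
         paste(unique(class[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Effective boat speed over a segment
#'
#' Downstream the water carries the boat (`avg + stream`); upstream it
#' opposes it (`avg - stream`, floored at the profile's minimum effective
#' speed). The result can never exceed `max_speed_kmh + stream` since the
#' cruising speed is bounded by the maximum.
#'
#' @param profile a [boat_profile()].
#' @param stream_kmh water stream speed in km/h (>= 0, vectorized).
#' @param direction `"downstream"` or `"upstream"`.
#' @return effective speed in km/h.
#' @export
effective_speed <- function(profile, stream_kmh,
                            direction = c("downstream", "upstream")) {
  direction <- match.arg(direction)
  if (any(stream_kmh < 0)) stop("stream speed must be >= 0")
  if (direction == "downstream") profile$avg_speed_kmh + stream_kmh
  else pmax(profile$avg_speed_kmh - stream_kmh,
            profile$min_effective_speed_kmh)
}

#' Per-direction travel times for river segments
#'
#' @param rivers a validated [river_layer()].
#' @param profile a [boat_profile()].
#' @param table a [stream_speed_table()].
#' @return data.frame with `seg_id`, `stream_kmh`, `tt_down_h`, `tt_up_h`.
#' @export
segment_travel_times <- function(rivers, profile = boat_profile(),
                                 table = stream_speed_table()) {
  stream <- stream_speed_for_class(table, rivers$stream_speed_class)
  data.frame(
    seg_id = rivers$seg_id,
    stream_kmh = stream,
    tt_down_h = rivers$length_km / effective_speed(profile, stream,
                                                   "downstream"),
    tt_up_h = rivers$length_km / effective_speed(profile, stream, "upstream"))
}

#' Default flow-regime code mapping
#'
#' Maps source regime codes to the three-level seasonal-variability enum.
#' Numeric GloRiC-style codes 1/2/3 and the literal labels are accepted.
#'
#' @param ... named overrides, `code = "level"`.
#' @return named character vector.
#' @export
flow_regime_map <- function(...) {
  map <- c("1" = "low", "2" = "medium", "3" = "high",
           low = "low", medium = "medium", high = "high")
  over <- c(...)
  if (length(over)) map[names(over)] <- over
  map
}

#' Classify flow-regime variability codes
#'
#' @param codes vector of source codes.
#' @param map code mapping from [flow_regime_map()].
#' @return character vector over `"low"`, `"medium"`, `"high"`.
#' @export
classify_flow_regime <- function(codes, map = flow_regime_map()) {
  out <- unname(map[as.character(codes)])
  if (anyNA(out))
    stop("unknown flow regime code: ",
         paste(unique(codes[is.na(out)]), collapse = ", "))
  if (!all(out %in% c("low", "medium", "high")))
    stop("flow regime map must target low/medium/high")
  out
}

#' Flag navigable segments by discharge
#'
#' Rivers at or above the discharge threshold are flagged navigable; the
#' rest are kept (flagged `FALSE`) so the network remains inspectable
#' rather than silently shrinking.
#'
#' @param rivers a validated [river_layer()].
#' @param min_discharge_cms threshold in m3/s (>= 0).
#' @return the layer with a logical `navigable` column.
#' @export
navigability_filter <- function(rivers, min_discharge_cms = 0) {
  if (min_discharge_cms < 0) stop("min_discharge_cms must be >= 0")
  rivers$navigable <- rivers$discharge_avg >= min_discharge_cms
  rivers
}

#' Emit OSM-schema routable records for river segments
#'
#' One record per segment, combining the junction incidence with the
#' transport attributes: per-direction travel times, boat speeds, stream
#' speed, flow regime, discharge and the navigability flag. Rivers are
#' bidirectional (`oneway = "B"`) with asymmetric per-direction times;
#' vessel width/weight/height limits are unrestricted; bridge, tunnel,
#' lanes and electricity are flagged "do not apply"; foot access is FALSE.
#'
#' @param rivers a validated [river_layer()].
#' @param junctions result of [build_junctions()] on the same layer.
#' @param profile a [boat_profile()].
#' @param table a [stream_speed_table()].
#' @param min_discharge_cms navigability threshold in m3/s.
#' @param fclass class label for river edges (kept distinct from road
#'   classes so scenario filtering is an attribute query).
#' @return a `routable_records` data.frame with a geometry list-column.
#' @export
to_osm_records <- function(rivers, junctions, profile = boat_profile(),
                           table = stream_speed_table(),
                           min_discharge_cms = 0,
                           fclass = "waterway_river") {
  stopifnot(inherits(junctions, "river_junctions"))
  rivers <- navigability_filter(rivers, min_discharge_cms)
  tt <- segment_travel_times(rivers, profile, table)
  inc <- junctions$incidence[match(rivers$seg_id, junctions$incidence$seg_id),
                             , drop = FALSE]
  nodes <- junctions$nodes
  rec <- data.frame(
    seg_id = rivers$seg_id,
    fclass = fclass,
    from_node = inc$from_node,
    to_node = inc$to_node,
    from_lon = nodes$lon[inc$from_node],
    from_lat = nodes$lat[inc$from_node],
    to_lon = nodes$lon[inc$to_node],
    to_lat = nodes$lat[inc$to_node],
    length_km = rivers$length_km,
    oneway = "B",
    maxspeed_kmh = profile$max_speed_kmh,
    avgspeed_kmh = profile$avg_speed_kmh,
    stream_speed_kmh = tt$stream_kmh,
    tt_down_h = tt$tt_down_h,
    tt_up_h = tt$tt_up_h,
    flow_regime_class = classify_flow_regime(rivers$flow_regime_class),
    discharge_avg = rivers$discharge_avg,
    navigable = rivers$navigable,
    foot_access = FALSE,
    width_limit = UNRESTRICTED,
    weight_limit = UNRESTRICTED,
    height_limit = UNRESTRICTED,
    bridge = DO_NOT_APPLY,
    tunnel = DO_NOT_APPLY,
    lanes = DO_NOT_APPLY,
    electricity = DO_NOT_APPLY)
  rec$geometry <- rivers$geometry
  class(rec) <- c("routable_records", "data.frame")
  rec
}

#' @export
print.routable_records <- function(x, ...) {
  cat("<routable_records> ", nrow(x), " river edges (",
      sum(x$navigable), " navigable)\n", sep = "")
  invisible(x)
}
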