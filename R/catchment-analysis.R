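# Per-facility travel-time catchment areas and the three-scenario coverage
# comparison (roads only / rivers only / combined). A facility is snapped to
# its nearest graph node within a tolerance; the catchment is the set of
# network edges reachable within the travel-time threshold from that node,
# with the last edge clipped proportionally, and the catchment polygon is
# the buffered union of the reached edge geometries.

#' Snap a facility to the nearest graph node
#'
#' @param graph a `transport_graph`.
#' @param lon,lat facility coordinates (WGS84).
#' @param max_snap_m maximum snapping distance in metres (default 2000).
#' @return list with `node_id` and `distance_m`, or `NULL` when no node is
#'   within range.
#' @export
snap_facility <- function(graph, lon, lat, max_snap_m = 2000) {
  stopifnot(inherits(graph, "transport_graph"), nrow(graph$nodes) > 0)
  d <- .dist_to_point_m(as.matrix(graph$nodes[, c("lon", "lat")]),
                        c(lon, lat))
  j <- which.min(d)
  if (d[j] > max_snap_m) return(NULL)
  list(node_id = graph$nodes$node_id[j], distance_m = unname(d[j]))
}

#' Travel-time service area of one facility
#'
#' Single-source shortest times are computed from the snapped node; an edge
#' is fully reached when both endpoints are within the threshold, and
#' partially reached with fraction `(threshold - entry_time) / edge_time`
#' when only its entry endpoint is. The polygon is the buffered union of
#' the (clipped) reached edge geometries.
#'
#' @param graph a `transport_graph`.
#' @param facility one-row `facility_layer` or a list with `facility_id`,
#'   `lon`, `lat`.
#' @param threshold_h travel-time threshold in hours (> 0).
#' @param max_snap_m snapping tolerance in metres.
#' @param buffer_m polygon buffer half-width in metres (default 250).
#' @param scenario label stored on the result.
#' @return a `catchment_result`.
#' @export
service_area <- function(graph, facility, threshold_h, max_snap_m = 2000,
                         buffer_m = 250, scenario = "combined") {
  stopifnot(threshold_h > 0)
  fid <- as.character(facility$facility_id[1])
  snap <- snap_facility(graph, facility$lon[1], facility$lat[1], max_snap_m)
  empty <- structure(list(facility_id = fid, scenario = scenario,
                          snapped_node = NULL, snap_distance_m = NA_real_,
                          threshold_h = threshold_h,
                          reached_edges = data.frame(),
                          polygon = list(), has_catchment = FALSE),
                     class = "catchment_result")
  if (is.null(snap)) return(empty)
  d <- travel_times_from(graph, snap$node_id)
  e <- graph$edges
  entry <- d[e$from]
  fraction <- pmin(1, pmax(0, (threshold_h - entry) / e$time_h))
  reached <- which(fraction > 0)
  if (length(reached) == 0) {
    # node reached but no edge: zero-length reach around the node itself
    node <- graph$nodes[graph$nodes$node_id == snap$node_id, ]
    poly <- buffer_polyline(matrix(c(node$lon, node$lat), ncol = 2),
                            width_m = buffer_m)
    res <- empty
    res$snapped_node <- snap$node_id
    res$snap_distance_m <- snap$distance_m
    res$polygon <- poly
    res$has_catchment <- TRUE
    res$reached_edges <- data.frame(from = snap$node_id, to = snap$node_id,
                                    mode = "node", fraction = 0)
    return(res)
  }
  re <- e[reached, c("from", "to", "mode", "ref_id"), drop = FALSE]
  re$fraction <- fraction[reached]
  rownames(re) <- NULL
  rings <- list()
  for (k in seq_along(reached)) {
    g <- e$geometry[[reached[k]]]
    clipped <- clip_polyline(g, re$fraction[k])
    rings <- c(rings, buffer_polyline(clipped, width_m = buffer_m))
  }
  structure(list(facility_id = fid, scenario = scenario,
                 snapped_node = snap$node_id,
                 snap_distance_m = snap$distance_m,
                 threshold_h = threshold_h,
                 reached_edges = re, polygon = rings, has_catchment = TRUE),
            class = "catchment_result")
}

#' @export
print.catchment_result <- function(x, ...) {
  cat("<catchment_result> facility ", x$facility_id, " (", x$scenario,
      "): ", if (x$has_catchment)
        paste0(nrow(x$reached_edges), " reached edges within ",
               x$threshold_h, " h") else "no catchment", "\n", sep = "")
  invisible(x)
}

#' Test whether one catchment polygon contains another
#'
#' Containment is evaluated at the ring-vertex level: every vertex of the
#' inner multipolygon must fall inside the outer multipolygon. Because
#' nested catchments share buffer boundaries exactly, the inner rings are
#' contracted toward their centroids by a small relative margin before
#' testing, so points lying on a shared boundary do not flip the answer.
#' An empty inner polygon is contained by anything.
#'
#' @param outer,inner `catchment_result` objects or ring lists.
#' @param shrink relative contraction applied to inner rings (default 1%).
#' @return logical.
#' @export
catchment_contains <- function(outer, inner, shrink = 0.01) {
  o <- if (inherits(outer, "catchment_result")) outer$polygon else outer
  i <- if (inherits(inner, "catchment_result")) inner$polygon else inner
  if (length(i) == 0) return(TRUE)
  if (length(o) == 0) return(FALSE)
  pts <- do.call(rbind, lapply(i, function(ring) {
    ctr <- colMeans(ring[-nrow(ring), , drop = FALSE])
    sweep(ring, 2, ctr) * (1 - shrink) + rep(ctr, each = nrow(ring))
  }))
  all(point_in_rings(pts, o))
}

#' Compare facility coverage across network scenarios
#'
#' Builds the roads-only, rivers-only and combined graphs, computes every
#' facility's catchment under each, and summarizes coverage: counts of
#' facilities with a catchment per scenario, the set newly covered by the
#' combined network relative to roads, and the percentage increase
#' `100 * (n_combined - n_roads) / n_roads`.
#'
#' @param river_records `routable_records`, or NULL for a roads-only study.
#' @param road_edges a [road_layer()], or NULL for a rivers-only study.
#' @param facilities a [facility_layer()].
#' @param threshold_h catchment travel-time threshold in hours (required).
#' @param connector_tolerance_m,walk_speed_kmh,default_road_speed_kmh
#'   forwarded to [build_graph()].
#' @param max_snap_m,buffer_m forwarded to [service_area()].
#' @return a `coverage_comparison` list: `summary` counts, `per_facility`
#'   table, `newly_covered` ids, `pct_increase` (NA when no road coverage),
#'   and all `catchments`.
#' @export
compare_scenarios <- function(river_records = NULL, road_edges = NULL,
                              facilities, threshold_h,
                              connector_tolerance_m = 500,
                              walk_speed_kmh = 5,
                              default_road_speed_kmh = 40,
                              max_snap_m = 2000, buffer_m = 250) {
  if (missing(threshold_h) || is.null(threshold_h))
    stop("threshold_h is required")
  stopifnot(threshold_h > 0)
  scen <- list()
  if (!is.null(road_edges) && nrow(road_edges) > 0)
    scen$roads <- build_graph(road_edges = road_edges,
                              default_road_speed_kmh = default_road_speed_kmh)
  if (!is.null(river_records) && nrow(river_records) > 0)
    scen$rivers <- build_graph(river_records = river_records)
  if (length(scen) == 0) stop("no network layer supplied")
  if (length(scen) == 2)
    scen$combined <- suppressWarnings(build_graph(
      river_records = river_records, road_edges = road_edges,
      connector_tolerance_m = connector_tolerance_m,
      walk_speed_kmh = walk_speed_kmh,
      default_road_speed_kmh = default_road_speed_kmh))

  catchments <- list()
  per_fac <- lapply(seq_len(nrow(facilities)), function(i) {
    fac <- facilities[i, ]
    row <- list(facility_id = fac$facility_id)
    for (s in names(scen)) {
      res <- service_area(scen[[s]], fac, threshold_h,
                          max_snap_m = max_snap_m, buffer_m = buffer_m,
                          scenario = s)
      catchments[[paste(fac$facility_id, s, sep = ".")]] <<- res
      row[[s]] <- res$has_catchment
    }
    as.data.frame(row)
  })
  per_fac <- do.call(rbind, per_fac)

  counts <- vapply(names(scen), function(s) sum(per_fac[[s]]), integer(1))
  summary <- list(n_facilities = nrow(facilities),
                  threshold_h = threshold_h)
  for (s in names(scen)) summary[[paste0("n_", s)]] <- unname(counts[s])
  newly <- character(0)
  pct <- NA_real_
  if (all(c("roads", "combined") %in% names(scen))) {
    newly <- per_fac$facility_id[per_fac$combined & !per_fac$roads]
    if (summary$n_roads > 0)
      pct <- 100 * (summary$n_combined - summary$n_roads) / summary$n_roads
  }
  structure(list(summary = summary, per_facility = per_fac,
                 newly_covered = newly, pct_increase = pct,
                 catchments = catchments),
            class = "coverage_comparison")
}

#' @export
print.coverage_comparison <- function(x, ...) {
  s <- x$summary
  cat("<coverage_comparison> ", s$n_facilities, " facilities, threshold ",
      s$threshold_h, " h\n", sep = "")
  for (nm in grep("^n_(roads|rivers|combined)$", names(s), value = TRUE))
    cat("  ", sub("n_", "", nm), ": ", s[[nm]], " catchment(s)\n", sep = "")
  if (length(x$newly_covered))
    cat("  newly covered by combined network: ",
        length(x$newly_covered), " (",
        paste(x$newly_covered, collapse = ", "), ")\n", sep = "")
  if (!is.na(x$pct_increase))
    cat("  coverage increase over roads: ",
        round(x$pct_increase, 1), "%\n", sep = "")
  invisible(x)
}

#' Write catchment polygons to GeoJSON
#'
#' One Polygon feature per buffered ring, tagged with facility id and
#' scenario.
#'
#' @param comparison a `coverage_comparison`.
#' @param path output GeoJSON path.
#' @export
write_catchment_polygons <- function(comparison, path) {
  feats <- list()
  for (res in comparison$catchments) {
    for (ring in res$polygon) {
      coords <- round(ring, .COORD_DIGITS)
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(facility_id = res$facility_id,
                          scenario = res$scenario,
                          threshold_h = res$threshold_h),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(coords)),
                                                  function(k) coords[k, ]))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the per-facility coverage table to CSV
#' @param comparison a `coverage_comparison`.
#' @param path output CSV path.
#' @export
write_coverage_table <- function(comparison, path) {
  utils::write.csv(comparison$per_facility, path, row.names = FALSE)
  invisible(path)
}
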