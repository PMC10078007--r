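# Directed travel-time-weighted multimodal graph. River records contribute
# two directed edges per segment (downstream weighted by tt_down_h, upstream
# by tt_up_h); road edges are weighted by length over maxspeed (with a
# configurable fallback when maxspeed is unknown); walking connectors join
# each road node to its nearest river node within a tolerance, symmetric in
# both directions. Node ids are namespaced "R<id>" (river junction) and
# "D<k>" (road node) so layers never collide.

#' Build a multimodal transport graph
#'
#' @param river_records optional `routable_records` from [to_osm_records()];
#'   non-navigable segments are excluded.
#' @param road_edges optional [road_layer()].
#' @param connector_tolerance_m maximum road-to-river walking distance for a
#'   connector edge, metres (default 500).
#' @param walk_speed_kmh walking speed on connector edges (default 5).
#' @param default_road_speed_kmh road speed used when `maxspeed_kmh` is 0 or
#'   missing (default 40).
#' @return a `transport_graph` (node table, directed edge table and the
#'   underlying weighted igraph).
#' @export
build_graph <- function(river_records = NULL, road_edges = NULL,
                        connector_tolerance_m = 500, walk_speed_kmh = 5,
                        default_road_speed_kmh = 40) {
  if (is.null(river_records) && is.null(road_edges))
    stop("need at least one of river_records, road_edges")

  nodes <- list(); edges <- list()

  if (!is.null(river_records) && nrow(river_records) > 0) {
    r <- river_records
    rn <- unique(data.frame(
      node_id = paste0("R", c(r$from_node, r$to_node)),
      lon = c(r$from_lon, r$to_lon), lat = c(r$from_lat, r$to_lat),
      mode = "river"))
    nodes$river <- rn[!duplicated(rn$node_id), ]
    nav <- r[r$navigable, , drop = FALSE]
    if (nrow(nav) > 0) {
      down <- data.frame(from = paste0("R", nav$from_node),
                         to = paste0("R", nav$to_node),
                         time_h = nav$tt_down_h, length_km = nav$length_km,
                         mode = "river", ref_id = as.character(nav$seg_id))
      down$geometry <- nav$geometry
      up <- data.frame(from = paste0("R", nav$to_node),
                       to = paste0("R", nav$from_node),
                       time_h = nav$tt_up_h, length_km = nav$length_km,
                       mode = "river", ref_id = as.character(nav$seg_id))
      up$geometry <- lapply(nav$geometry, function(g) g[nrow(g):1, ,
                                                        drop = FALSE])
      keep_up <- is.finite(up$time_h)   # non-navigable-upstream sentinel
      edges$river <- rbind(down, up[keep_up, , drop = FALSE])
    }
  }

  if (!is.null(road_edges) && nrow(road_edges) > 0) {
    ends <- do.call(rbind, lapply(road_edges$geometry, function(g)
      rbind(g[1, ], g[nrow(g), ])))
    cl <- grid_cluster(ends, tolerance_m = 1)
    from_i <- cl$assignment[seq(1, 2 * nrow(road_edges), by = 2)]
    to_i <- cl$assignment[seq(2, 2 * nrow(road_edges), by = 2)]
    nodes$road <- data.frame(node_id = paste0("D", seq_len(nrow(cl$centers))),
                             lon = cl$centers[, "lon"],
                             lat = cl$centers[, "lat"], mode = "road")
    speed <- ifelse(road_edges$maxspeed_kmh > 0, road_edges$maxspeed_kmh,
                    default_road_speed_kmh)
    fwd <- data.frame(from = paste0("D", from_i), to = paste0("D", to_i),
                      time_h = road_edges$length_km / speed,
                      length_km = road_edges$length_km, mode = "road",
                      ref_id = road_edges$osm_id)
    fwd$geometry <- road_edges$geometry
    rev <- fwd
    rev$from <- fwd$to; rev$to <- fwd$from
    rev$geometry <- lapply(road_edges$geometry,
                           function(g) g[nrow(g):1, , drop = FALSE])
    keep_f <- road_edges$oneway %in% c("B", "F")
    keep_r <- road_edges$oneway %in% c("B", "T")
    edges$road <- rbind(fwd[keep_f, , drop = FALSE],
                        rev[keep_r, , drop = FALSE])
  }

  # walking connectors: each road node to its nearest river node in range
  if (!is.null(nodes$river) && !is.null(nodes$road)) {
    rivpts <- as.matrix(nodes$river[, c("lon", "lat")])
    conn <- lapply(seq_len(nrow(nodes$road)), function(i) {
      d <- .dist_to_point_m(rivpts,
                            c(nodes$road$lon[i], nodes$road$lat[i]))
      j <- which.min(d)
      if (d[j] > connector_tolerance_m) return(NULL)
      t_h <- (d[j] / 1000) / walk_speed_kmh
      g <- rbind(c(nodes$road$lon[i], nodes$road$lat[i]),
                 c(nodes$river$lon[j], nodes$river$lat[j]))
      out <- data.frame(from = c(nodes$road$node_id[i],
                                 nodes$river$node_id[j]),
                        to = c(nodes$river$node_id[j],
                               nodes$road$node_id[i]),
                        time_h = t_h, length_km = d[j] / 1000,
                        mode = "connector", ref_id = NA_character_)
      out$geometry <- list(g, g[2:1, , drop = FALSE])
      out
    })
    conn <- do.call(rbind, conn)
    if (is.null(conn)) {
      warning("no road-river connector found within ",
              connector_tolerance_m, " m; layers remain disjoint")
    } else {
      edges$connector <- conn
      message(nrow(conn) / 2, " road-river connector(s) created")
    }
  }

  node_df <- do.call(rbind, nodes)
  rownames(node_df) <- NULL
  edge_df <- do.call(rbind, edges)
  rownames(edge_df) <- NULL
  if (is.null(edge_df) || nrow(edge_df) == 0)
    stop("graph has no edges")
  if (any(!is.finite(edge_df$time_h) | edge_df$time_h <= 0))
    stop("all edge times must be finite and > 0")
  g <- igraph::graph_from_data_frame(
    edge_df[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = node_df$node_id))
  igraph::E(g)$weight <- edge_df$time_h
  structure(list(nodes = node_df, edges = edge_df, igraph = g),
            class = "transport_graph")
}

#' @export
print.transport_graph <- function(x, ...) {
  tab <- table(x$edges$mode)
  cat("<transport_graph> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Shortest travel time between two nodes
#'
#' Minimal summed edge time over the directed graph. Returns `Inf` (the
#' unreachable sentinel) when no path exists.
#'
#' @param graph a `transport_graph`.
#' @param origin,dest node ids present in the graph.
#' @return travel time in hours, or `Inf`.
#' @export
shortest_time <- function(graph, origin, dest) {
  stopifnot(inherits(graph, "transport_graph"))
  unknown <- setdiff(c(origin, dest), graph$nodes$node_id)
  if (length(unknown))
    stop("unknown node id: ", paste(unknown, collapse = ", "))
  as.numeric(igraph::distances(graph$igraph, v = origin, to = dest,
                               mode = "out"))
}

#' Travel times from one node to all nodes
#' @param graph a `transport_graph`.
#' @param origin node id.
#' @return named numeric vector of hours (Inf where unreachable).
#' @export
travel_times_from <- function(graph, origin) {
  stopifnot(inherits(graph, "transport_graph"))
  if (!origin %in% graph$nodes$node_id)
    stop("unknown node id: ", origin)
  d <- igraph::distances(graph$igraph, v = origin, mode = "out")
  stats::setNames(as.numeric(d), colnames(d))
}

#' Export the directed edge list to CSV
#' @param graph a `transport_graph`.
#' @param path output CSV path.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.csv(graph$edges[, c("from", "to", "time_h", "length_km",
                                   "mode", "ref_id")],
                   path, row.names = FALSE)
  invisible(path)
}
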