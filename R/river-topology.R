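# Junction reconstruction. HydroSHEDS-style layers link segments by a
# next-downstream id but carry no junction coordinates; routing needs a node
# at every confluence. Segment endpoints are clustered on a tolerance grid
# (order-independent), each cluster becomes one junction node, and every
# segment receives a from_node (upstream end) and to_node (downstream end).

#' Extract the upstream and downstream endpoints of a segment geometry
#'
#' By the digitization convention the first vertex is the upstream end and
#' the last vertex the downstream end.
#'
#' @param geometry a two-column (lon, lat) vertex matrix with >= 2 vertices.
#' @return list with `upstream` and `downstream`, each a named (lon, lat)
#'   vector.
#' @export
extract_endpoints <- function(geometry) {
  geometry <- as.matrix(geometry)
  if (nrow(geometry) < 2)
    stop("degenerate geometry: need at least 2 vertices")
  list(upstream = c(lon = geometry[1, 1], lat = geometry[1, 2]),
       downstream = c(lon = geometry[nrow(geometry), 1],
                      lat = geometry[nrow(geometry), 2]))
}

#' Build junction nodes and segment incidences
#'
#' Clusters all segment endpoints with a metric tolerance (grid-hash
#' rounding, so the result is independent of segment order) and assigns node
#' ids in lexicographic (lon, lat) order. Warns when a `next_down` pair does
#' not share a node, which indicates endpoint jitter beyond the tolerance or
#' a mid-segment confluence (see [split_mid_confluences()]).
#'
#' @param rivers a validated [river_layer()].
#' @param tolerance_m endpoint merge tolerance in metres (default 1).
#' @return a `river_junctions` list with `nodes` (node_id, lon, lat, degree)
#'   and `incidence` (seg_id, from_node, to_node).
#' @export
build_junctions <- function(rivers, tolerance_m = 1) {
  validate_river_layer(rivers)
  n <- nrow(rivers)
  if (n == 0) {
    return(structure(list(
      nodes = data.frame(node_id = integer(0), lon = numeric(0),
                         lat = numeric(0), degree = integer(0)),
      incidence = data.frame(seg_id = integer(0), from_node = integer(0),
                             to_node = integer(0)),
      tolerance_m = tolerance_m), class = "river_junctions"))
  }
  ends <- lapply(rivers$geometry, extract_endpoints)
  pts <- rbind(do.call(rbind, lapply(ends, `[[`, "upstream")),
               do.call(rbind, lapply(ends, `[[`, "downstream")))
  cl <- grid_cluster(pts, tolerance_m)
  from_node <- cl$assignment[seq_len(n)]
  to_node <- cl$assignment[n + seq_len(n)]
  degree <- tabulate(c(from_node, to_node), nbins = nrow(cl$centers))
  nodes <- data.frame(node_id = seq_len(nrow(cl$centers)),
                      lon = cl$centers[, "lon"], lat = cl$centers[, "lat"],
                      degree = degree)
  incidence <- data.frame(seg_id = rivers$seg_id, from_node = from_node,
                          to_node = to_node)
  # a downstream link should share a node with its target segment
  idx <- match(rivers$next_down, rivers$seg_id)
  linked <- which(rivers$next_down != 0 & !is.na(idx))
  bad <- linked[to_node[linked] != from_node[idx[linked]] &
                  to_node[linked] != to_node[idx[linked]]]
  if (length(bad))
    warning("next_down pair(s) not sharing a junction node: seg_id ",
            paste(rivers$seg_id[bad], collapse = ", "),
            " (endpoint jitter beyond tolerance or mid-segment confluence)")
  structure(list(nodes = nodes, incidence = incidence,
                 tolerance_m = tolerance_m),
            class = "river_junctions")
}

#' @export
print.river_junctions <- function(x, ...) {
  cat("<river_junctions> ", nrow(x$nodes), " nodes / ",
      nrow(x$incidence), " segments (tolerance ",
      x$tolerance_m, " m)\n", sep = "")
  invisible(x)
}

#' Split segments at mid-polyline confluences
#'
#' When a segment's downstream endpoint touches the interior of its
#' next-downstream segment's polyline (rather than one of its endpoints),
#' the target segment is split at the touch point into two child edges that
#' inherit its attributes, with lengths and discharge kept and `length_km`
#' prorated by arc length. This guarantees a junction node exists at every
#' confluence before [build_junctions()].
#'
#' @param rivers a validated [river_layer()].
#' @param tolerance_m touch tolerance in metres.
#' @return a `river_layer`, possibly with more segments than the input; new
#'   segments receive ids above the current maximum.
#' @export
split_mid_confluences <- function(rivers, tolerance_m = 1) {
  validate_river_layer(rivers)
  repeat {
    hit <- find_mid_confluence(rivers, tolerance_m)
    if (is.null(hit)) return(rivers)
    rivers <- split_segment_at(rivers, hit$target, hit$vertex)
  }
}

# find the first (segment, target) pair whose downstream endpoint touches the
# interior of the target polyline; returns the touch vertex index on target
find_mid_confluence <- function(rivers, tolerance_m) {
  idx <- match(rivers$next_down, rivers$seg_id)
  for (i in seq_len(nrow(rivers))) {
    t <- idx[i]
    if (is.na(t)) next
    p <- rivers$geometry[[i]][nrow(rivers$geometry[[i]]), ]
    tg <- rivers$geometry[[t]]
    d_end <- .dist_to_point_m(tg[c(1, nrow(tg)), , drop = FALSE], p)
    if (any(d_end <= tolerance_m)) next  # touches an endpoint: normal case
    d <- .dist_to_point_m(tg, p)
    k <- which(d <= tolerance_m)
    k <- k[k > 1 & k < nrow(tg)]
    if (length(k)) return(list(target = t, vertex = k[1]))
  }
  NULL
}

split_segment_at <- function(rivers, t, k) {
  g <- rivers$geometry[[t]]
  up_g <- g[seq_len(k), , drop = FALSE]
  down_g <- g[k:nrow(g), , drop = FALSE]
  frac <- polyline_length_km(up_g) /
    (polyline_length_km(up_g) + polyline_length_km(down_g))
  new_id <- max(rivers$seg_id) + 1L
  row <- as.data.frame(rivers)[t, ]
  up_row <- row
  up_row$seg_id <- new_id
  up_row$next_down <- row$seg_id
  up_row$length_km <- row$length_km * frac
  up_row$geometry <- list(up_g)
  rivers$geometry[[t]] <- down_g
  rivers$length_km[t] <- row$length_km * (1 - frac)
  # segments that drained into t's upstream end now drain into the new child
  head_pt <- g[1, ]
  feeders <- which(rivers$next_down == row$seg_id)
  for (f in feeders) {
    fg <- rivers$geometry[[f]]
    if (.dist_to_point_m(matrix(head_pt, ncol = 2), fg[nrow(fg), ]) <= 1 ||
        .dist_to_point_m(matrix(fg[nrow(fg), ], ncol = 2), head_pt) <= 1)
      rivers$next_down[f] <- new_id
  }
  out <- rbind(as.data.frame(rivers), up_row)
  class(out) <- c("river_layer", "data.frame")
  validate_river_layer(out)
  out
}

#' Diagnose river network topology
#'
#' Report-only check of the connectivity built by [build_junctions()]:
#' cycles in the downstream relation (there must be none), number of
#' connected components of the junction graph, and `next_down` pairs whose
#' geometry does not share a node.
#'
#' @param rivers a validated [river_layer()].
#' @param junctions result of [build_junctions()].
#' @return a `topology_report` list with `cycles`, `n_components`,
#'   `mismatches`, and `ok` (TRUE when the report is empty).
#' @export
validate_topology <- function(rivers, junctions) {
  cycles <- downstream_cycles(rivers$seg_id, rivers$next_down)
  inc <- junctions$incidence
  n_components <- if (nrow(inc) == 0) 0L else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = inc$from_node, to = inc$to_node),
      directed = FALSE,
      vertices = data.frame(name = junctions$nodes$node_id))
    igraph::count_components(g)
  }
  idx <- match(rivers$next_down, rivers$seg_id)
  linked <- which(rivers$next_down != 0 & !is.na(idx))
  mm <- linked[inc$to_node[linked] != inc$from_node[idx[linked]] &
                 inc$to_node[linked] != inc$to_node[idx[linked]]]
  mismatches <- data.frame(seg_id = rivers$seg_id[mm],
                           next_down = rivers$next_down[mm])
  structure(list(cycles = cycles, n_components = n_components,
                 mismatches = mismatches,
                 ok = length(cycles) == 0 && n_components <= 1 &&
                   nrow(mismatches) == 0),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report> ",
      length(x$cycles), " cycle(s), ",
      x$n_components, " component(s), ",
      nrow(x$mismatches), " next_down/geometry mismatch(es)\n", sep = "")
  invisible(x)
}

#' Export the junction node matrix to CSV
#'
#' Writes the per-node reference table (node_id, lon, lat, degree) used to
#' define river connectivity.
#'
#' @param junctions a `river_junctions` object.
#' @param path output CSV path.
#' @export
write_node_matrix <- function(junctions, path) {
  utils::write.csv(junctions$nodes, path, row.names = FALSE)
  invisible(path)
}
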