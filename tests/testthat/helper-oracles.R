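# Independent oracles and small fixture builders used across test files.

# Exhaustive shortest-path oracle: enumerate every simple path by recursive
# DFS over a plain edge data.frame (from, to, time_h). Independent of the
# package's igraph-based routing.
brute_force_time <- function(edges, origin, dest) {
  best <- Inf
  walk <- function(node, visited, t) {
    if (t >= best) return()
    if (node == dest) { best <<- min(best, t); return() }
    out <- edges[edges$from == node & !(edges$to %in% visited), ,
                 drop = FALSE]
    for (k in seq_len(nrow(out)))
      walk(out$to[k], c(visited, out$to[k]), t + out$time_h[k])
  }
  walk(origin, origin, 0)
  best
}

# a random directed road network with <= n_nodes nodes, returned as a
# road_layer plus the coordinates of its nodes (oneway = "F" keeps the
# digitized direction, so the graph is genuinely directed)
random_road_net <- function(seed, n_nodes = 8, n_edges = 14) {
  withr::with_seed(seed, {
    pts <- cbind(lon = runif(n_nodes, -60.5, -60.3),
                 lat = runif(n_nodes, -3.2, -3.0))
    pairs <- unique(t(replicate(n_edges, sample.int(n_nodes, 2))))
    geoms <- lapply(seq_len(nrow(pairs)), function(k)
      rbind(pts[pairs[k, 1], ], pts[pairs[k, 2], ]))
    list(roads = road_layer(osm_id = sprintf("e%02d", seq_len(nrow(pairs))),
                            geometry = geoms, oneway = "F",
                            maxspeed_kmh = runif(nrow(pairs), 20, 80)),
         # only nodes that occur in at least one edge exist in the graph
         pts = pts[sort(unique(as.vector(pairs))), , drop = FALSE])
  })
}

# node id in a transport_graph closest to a coordinate (exact by construction)
node_at <- function(graph, pt) {
  snap_facility(graph, pt[1], pt[2], max_snap_m = 5)$node_id
}

# straight two-segment river chain flowing south (upstream -> downstream),
# with a given stream-speed class
river_chain <- function(stream_class = 2L, n = 2) {
  lat <- seq(-2.8, by = -0.1, length.out = n + 1)
  geoms <- lapply(seq_len(n), function(i)
    rbind(c(-60, lat[i]), c(-60, lat[i + 1])))
  river_layer(seg_id = seq_len(n),
              next_down = c(seq_len(n)[-1], 0L),
              geometry = geoms, discharge_avg = seq(n, 1),
              stream_speed_class = stream_class)
}
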