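# Synthetic fixture generator: dendritic river trees with downstream-
# accumulating discharge (HydroSHEDS-like), rectangular road grids
# (GeoFabrik-like) offset from the rivers, and facility layouts with known
# ground-truth reachability. Every generator draws from its own explicitly
# seeded random stream (withr::with_seed), never from ambient global state.

#' Specification for a synthetic fixture
#'
#' @param seed integer seed for the generator's private random stream.
#' @param n_segments number of river segments (>= 1).
#' @param branch_prob probability that a confluence forms where a segment
#'   already has one upstream child.
#' @param bbox numeric (lon_min, lat_min, lon_max, lat_max); default is a
#'   small near-equatorial box so geodesic and planar distances agree to
#'   within a fraction of a percent, which keeps hand-checks simple.
#' @param discharge_headwater_cms local discharge contribution of each
#'   segment in m3/s; accumulates downstream.
#' @param regime_probs probabilities of the low/medium/high flow-regime
#'   classes; the default (0.05, 0.86, 0.09) mirrors the class shares
#'   observed across Amazon-basin reaches.
#' @param road_grid list with `rows`, `cols`, `spacing_km` and optional
#'   `origin` (lon, lat of the south-west grid corner); by default the grid
#'   is offset east of the river bbox, beyond snapping range, creating
#'   river-only zones.
#' @param facility_plan named counts `c(on_road, on_river, off_network)`.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_segments = 50, branch_prob = 0.3,
                         bbox = c(-60.5, -3.5, -59.5, -2.5),
                         discharge_headwater_cms = 5,
                         regime_probs = c(low = 0.05, medium = 0.86,
                                          high = 0.09),
                         road_grid = list(rows = 4, cols = 4,
                                          spacing_km = 3, origin = NULL),
                         facility_plan = c(on_road = 6, on_river = 3,
                                           off_network = 1)) {
  stopifnot(n_segments >= 1, branch_prob >= 0, branch_prob <= 1,
            bbox[3] > bbox[1], bbox[4] > bbox[2],
            discharge_headwater_cms > 0)
  if (abs(sum(regime_probs) - 1) > 1e-9 || any(regime_probs < 0))
    stop("regime_probs must be non-negative and sum to 1")
  structure(list(seed = as.integer(seed), n_segments = as.integer(n_segments),
                 branch_prob = branch_prob, bbox = bbox,
                 discharge_headwater_cms = discharge_headwater_cms,
                 regime_probs = regime_probs, road_grid = road_grid,
                 facility_plan = facility_plan),
            class = "fixture_spec")
}

.KM_PER_DEG <- 111.32

#' Generate a dendritic river tree
#'
#' Grows a rooted tree upstream from a single outlet: each new segment
#' attaches its downstream end exactly at the upstream endpoint of an
#' existing segment (so endpoint snapping is exact), a second child at the
#' same point forming a confluence with probability `branch_prob`. Segment
#' geometry is a jittered polyline kept inside the bbox. Discharge
#' accumulates downstream: each segment carries its own headwater
#' contribution plus the sum of its children's discharges, so a parent's
#' discharge always exceeds each child's. Flow-regime classes are sampled
#' from `regime_probs`.
#'
#' @param spec a [fixture_spec()].
#' @return a validated [river_layer()] whose outlet segment has
#'   `next_down = 0`.
#' @export
generate_river_tree <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_segments
  bbox <- spec$bbox
  withr::with_seed(spec$seed, {
    geometry <- vector("list", n)
    next_down <- integer(n)
    up_pt <- matrix(0, n, 2)
    up_dir <- numeric(n)
    nchild <- integer(n)
    # outlet near the southern edge, growing northwards
    outlet <- c(mean(bbox[c(1, 3)]), bbox[2] + 0.08 * (bbox[4] - bbox[2]))
    g <- grow_upstream(outlet, stats::runif(1, 70, 110) * pi / 180,
                       stats::runif(1, 2, 8), bbox)
    geometry[[1]] <- g$geom
    up_pt[1, ] <- g$geom[1, ]
    up_dir[1] <- g$heading
    next_down[1] <- 0L
    for (i in seq_len(n)[-1]) {
      j <- NA_integer_
      for (try in 1:50) {
        cand <- sample.int(i - 1, 1)
        if (nchild[cand] == 0 ||
            (nchild[cand] == 1 && stats::runif(1) < spec$branch_prob)) {
          j <- cand; break
        }
      }
      if (is.na(j)) j <- which(nchild[seq_len(i - 1)] == 0)[1]
      turn <- if (nchild[j] == 0) stats::runif(1, -30, 30) else
        sample(c(-1, 1), 1) * stats::runif(1, 35, 70)
      g <- grow_upstream(up_pt[j, ], up_dir[j] + turn * pi / 180,
                         stats::runif(1, 2, 8), bbox)
      geometry[[i]] <- g$geom
      up_pt[i, ] <- g$geom[1, ]
      up_dir[i] <- g$heading
      next_down[i] <- j
      nchild[j] <- nchild[j] + 1L
    }
    # discharge: own headwater contribution + sum over upstream children
    contrib <- spec$discharge_headwater_cms * stats::runif(n, 0.5, 1.5)
    discharge <- accumulate_discharge(next_down, contrib)
    regime <- sample(names(spec$regime_probs), n, replace = TRUE,
                     prob = spec$regime_probs)
    stream_class <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
    river_layer(seg_id = seq_len(n), next_down = next_down,
                geometry = geometry, length_km = NULL,
                discharge_avg = round(discharge, 3),
                flow_regime_class = regime,
                stream_speed_class = stream_class)
  })
}

# random-walk a polyline upstream from `start`, total length `len_km`,
# staying inside bbox by reflecting the heading at the walls; returns the
# geometry digitized upstream -> downstream plus the final upstream heading
grow_upstream <- function(start, heading, len_km, bbox) {
  nv <- sample(3:6, 1)
  step <- len_km / (nv - 1) / .KM_PER_DEG
  pts <- matrix(0, nv, 2)
  pts[1, ] <- start
  for (k in 2:nv) {
    heading <- heading + stats::runif(1, -20, 20) * pi / 180
    dx <- step * cos(heading)
    dy <- step * sin(heading)
    nxt <- pts[k - 1, ] + c(dx, dy)
    if (nxt[1] < bbox[1] || nxt[1] > bbox[3]) { dx <- -dx }
    if (nxt[2] < bbox[2] || nxt[2] > bbox[4]) { dy <- -dy }
    heading <- atan2(dy, dx)
    nxt <- pts[k - 1, ] + c(dx, dy)
    nxt[1] <- min(max(nxt[1], bbox[1]), bbox[3])
    nxt[2] <- min(max(nxt[2], bbox[2]), bbox[4])
    pts[k, ] <- nxt
  }
  list(geom = pts[nv:1, , drop = FALSE], heading = heading)
}

# sum contributions downstream over the next_down forest (children first)
accumulate_discharge <- function(next_down, contrib) {
  n <- length(contrib)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; v <- i
    while (next_down[v] != 0L) { v <- next_down[v]; d <- d + 1L }
    depth[i] <- d
  }
  discharge <- contrib
  for (i in order(depth, decreasing = TRUE)) {
    if (next_down[i] != 0L)
      discharge[next_down[i]] <- discharge[next_down[i]] + discharge[i]
  }
  discharge
}

#' Generate a rectangular road grid
#'
#' A rows x cols lattice of bidirectional road edges with `spacing_km`
#' spacing (so `2*rows*cols - rows - cols` edges). By default the grid is
#' placed east of the river bbox with a gap larger than the default
#' facility-snapping and connector tolerances, creating genuinely
#' river-only territory.
#'
#' @param spec a [fixture_spec()].
#' @return a validated [road_layer()].
#' @export
generate_road_grid <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rg <- spec$road_grid
  origin <- rg$origin
  if (is.null(origin))
    origin <- c(spec$bbox[3] + 0.06, spec$bbox[2] + 0.1)
  sp_deg <- rg$spacing_km / .KM_PER_DEG
  node_xy <- function(r, c) c(origin[1] + (c - 1) * sp_deg,
                              origin[2] + (r - 1) * sp_deg)
  withr::with_seed(spec$seed + 1L, {
    geoms <- list(); maxspeed <- numeric(0)
    for (r in seq_len(rg$rows)) for (c in seq_len(rg$cols)) {
      if (c < rg$cols)
        geoms[[length(geoms) + 1]] <- rbind(node_xy(r, c), node_xy(r, c + 1))
      if (r < rg$rows)
        geoms[[length(geoms) + 1]] <- rbind(node_xy(r, c), node_xy(r + 1, c))
    }
    maxspeed <- sample(c(0, 40, 60), length(geoms), replace = TRUE)
    road_layer(osm_id = sprintf("osm_%03d", seq_along(geoms)),
               fclass = "secondary", geometry = geoms, oneway = "B",
               maxspeed_kmh = maxspeed)
  })
}

#' Generate facilities with ground-truth reachability labels
#'
#' Places facilities according to the fixture plan: on road lattice nodes
#' (road-reachable), on river junction nodes beyond snapping range of any
#' road (river-only), and beyond snapping range of every network node
#' (off-network). The `expected` column carries the ground-truth label
#' (`"road"`, `"river"`, `"off"`), which the full pipeline must recover.
#'
#' @param spec a [fixture_spec()].
#' @param rivers river layer from [generate_river_tree()].
#' @param roads road layer from [generate_road_grid()].
#' @param max_snap_m the snapping tolerance the labels are guaranteed
#'   against (default 2000).
#' @return a `facility_layer` with an extra `expected` column.
#' @export
generate_facilities <- function(spec, rivers, roads, max_snap_m = 2000) {
  stopifnot(inherits(spec, "fixture_spec"))
  plan <- spec$facility_plan
  junc <- build_junctions(rivers)
  riv_nodes <- as.matrix(junc$nodes[, c("lon", "lat")])
  road_pts <- unique(do.call(rbind, lapply(roads$geometry, function(g)
    g[c(1, nrow(g)), , drop = FALSE])))
  withr::with_seed(spec$seed + 2L, {
    # on-road: distinct lattice nodes, must be out of river snapping range
    ok_road <- vapply(seq_len(nrow(road_pts)), function(i)
      min(.dist_to_point_m(riv_nodes, road_pts[i, ])) > 2 * max_snap_m,
      logical(1))
    cand <- which(ok_road)
    if (length(cand) < plan[1]) stop("not enough road nodes beyond river range")
    pick_road <- road_pts[sample(cand, plan[1]), , drop = FALSE]
    # river-only: junction nodes out of road snapping range
    ok_riv <- vapply(seq_len(nrow(riv_nodes)), function(i)
      min(.dist_to_point_m(road_pts, riv_nodes[i, ])) > 2 * max_snap_m,
      logical(1))
    cand <- which(ok_riv)
    if (length(cand) < plan[2]) stop("not enough river nodes beyond road range")
    pick_riv <- riv_nodes[sample(cand, plan[2]), , drop = FALSE]
    # off-network: west of the river bbox, far from every node
    all_pts <- rbind(riv_nodes, road_pts)
    pick_off <- matrix(0, 0, 2)
    k <- 0
    while (nrow(pick_off) < plan[3] && k < 1000) {
      k <- k + 1
      p <- c(spec$bbox[1] - 0.1 - 0.03 * k, spec$bbox[2] - 0.1)
      if (min(.dist_to_point_m(all_pts, p)) > 2 * max_snap_m)
        pick_off <- rbind(pick_off, p)
    }
    pts <- rbind(pick_road, pick_riv, pick_off)
    labels <- rep(c("road", "river", "off"), times = plan)
    fac <- facility_layer(sprintf("chc_%02d", seq_len(nrow(pts))),
                          lon = pts[, 1], lat = pts[, 2])
    fac$expected <- labels
    fac
  })
}

#' Materialize a named fixture scenario
#'
#' * `"y-network"` — a deterministic 3-segment Y: two tributaries joining a
#'   mainstem at one confluence (4 junction nodes, confluence degree 3).
#' * `"random-tree"` — a seeded dendritic tree with default spec.
#' * `"archipelago"` — rivers, an offset road grid, and a facility plan of
#'   6 road-reachable, 3 river-only and 1 off-network facility.
#'
#' @param name scenario name.
#' @param seed seed forwarded to the spec.
#' @return a `river_layer` for the river-only scenarios, or a list with
#'   `rivers`, `roads`, `facilities` for `"archipelago"`.
#' @export
fixture_scenario <- function(name = c("y-network", "random-tree",
                                      "archipelago"), seed = 1) {
  name <- match.arg(name)
  if (name == "y-network") {
    conf <- c(-60.0, -3.0)
    return(river_layer(
      seg_id = 1:3, next_down = c(0L, 1L, 1L),
      geometry = list(rbind(conf, c(-60.0, -3.05), c(-60.0, -3.1)),
                      rbind(c(-60.05, -2.92), c(-60.02, -2.96), conf),
                      rbind(c(-59.95, -2.92), c(-59.98, -2.96), conf)),
      discharge_avg = c(10, 5, 5),
      flow_regime_class = c("medium", "medium", "low"),
      stream_speed_class = c(2L, 1L, 1L)))
  }
  if (name == "random-tree")
    return(generate_river_tree(fixture_spec(seed = seed)))
  spec <- fixture_spec(seed = seed, n_segments = 40)
  rivers <- generate_river_tree(spec)
  roads <- generate_road_grid(spec)
  facilities <- generate_facilities(spec, rivers, roads)
  list(spec = spec, rivers = rivers, roads = roads, facilities = facilities)
}
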