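---
title: "From hydrography to routable rivers: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hydrography to routable rivers: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverroutes)
```

## The problem

Hydrography products of the HydroSHEDS/HydroRIVERS family represent a river
network as polyline segments, each carrying a unique id, the id of the next
segment downstream (`0` at an outlet), a length, an average discharge, and —
via the GloRiC classification — hydrological classes such as seasonal
flow-regime variability and stream velocity. What they lack is everything a
router needs: junction coordinates, connectivity incidences, speeds, and
travel times. This package converts such a layer into a routable,
OSM-schema-compatible transport network and uses it, together with a
GeoFabrik-style road layer, to compute travel-time catchment areas around
healthcare facilities.

## Junction reconstruction

Segments are digitized upstream → downstream, so the first vertex is the
upstream endpoint and the last the downstream endpoint. All `2n` endpoints
of `n` segments are clustered and each cluster becomes a junction node.

Numerical choices:

* **Merge tolerance, 1 m.** Hydrography endpoints are grid-snapped, so
  exact coincidences dominate; 1 m absorbs floating-point jitter (and the
  6-decimal coordinate rounding used by the writers, ≈ 0.11 m) without ever
  merging genuinely distinct junctions.
* **Grid-hash clustering, not nearest-neighbour.** Coordinates are rounded
  to the tolerance grid and identical cells merged. Unlike greedy
  nearest-neighbour chaining, this is independent of segment order, so node
  ids and coordinates are reproducible for any input permutation. Node ids
  are assigned in lexicographic (lon, lat) order for the same reason.
* **Mid-segment confluences.** If a segment's downstream endpoint touches
  the *interior* of its downstream target's polyline, `split_mid_confluences`
  splits the target at the touch vertex into two children that inherit its
  attributes with lengths prorated by arc length — routing requires a node
  at every confluence. Pairs that still fail to share a node are surfaced
  as a warning and listed in the `validate_topology` report rather than
  silently repaired.

For a connected dendritic tree with exact snapping these invariants hold
and are enforced in the test suite: node count = segment count + 1, degree
sum = 2 × segment count, and exactly one node (the outlet) has no outgoing
downstream segment.

## Travel-time model

A single boat profile describes the vessel:

| parameter | default | unit | meaning |
|---|---|---|---|
| `avg_speed_kmh` | 18.52 | km/h | cruising speed of a standard motorized riverboat |
| `max_speed_kmh` | 37 | km/h | upper speed bound stored on every record |
| `min_effective_speed_kmh` | 1 | km/h | floor for upstream effective speed |

The default cruising and maximum speeds are the standard figures for
motorized boats on Amazon rivers. The effective speed over a segment is the
boat speed plus the water stream speed downstream and minus it upstream:

$$ t_{down} = \frac{L}{v_{boat} + v_s}, \qquad
   t_{up} = \frac{L}{\max(v_{boat} - v_s,\; v_{min})} $$

so `t_down < t_up` whenever `v_s > 0` (downstream dominance, a tested
invariant). Two deliberate choices:

* **Stream-speed magnitudes.** The velocity classes carried by the source
  data are ordinal; no canonical km/h values exist for them. The default
  `stream_speed_table()` (class 1 → 0.5, 2 → 1.5, 3 → 3.0 km/h) is a
  modelling choice — slow lowland reaches to fast upper courses — and is
  fully overridable; the table is validated to be non-negative and
  monotone in the class index.
* **Upstream floor instead of an upstream-impassable sentinel.** When the
  stream speed reaches the boat speed, marking the segment one-way would
  silently disconnect whole subnetworks. The default floors the upstream
  speed at 1 km/h; the emitted `tt_up_h` can still carry a non-finite
  sentinel, which the graph builder honours by dropping only that directed
  edge.

Navigability is a discharge filter: segments with
`discharge_avg >= min_discharge_cms` are flagged navigable, the rest kept
but flagged `FALSE` (and excluded from graphs). Flagging instead of
deleting keeps the converted layer inspectable and makes the navigable set
trivially monotone in the threshold.

Emitted records follow the GeoFabrik routable-shapefile schema under fixed
DBF-legal names (≤ 10 characters; see `routable_field_names()`). Fields
with no river meaning — bridge, tunnel, lanes, electricity — hold the
`"do not apply"` sentinel; vessel width/weight/height limits hold
`"unrestricted"`, since river breadth imposes no practical vessel-size
restriction in this setting; rivers are emitted bidirectional
(`oneway = "B"`) with the asymmetry carried by the two time fields, which
matches OSM semantics while preserving directionality for routing.

## The multimodal graph

Each navigable river segment contributes two directed edges (weights
`tt_down_h`, `tt_up_h`); each road edge contributes one or two directed
edges (weight `length_km / maxspeed`, with a 40 km/h default where the
speed limit is 0/unknown, and the GeoFabrik `oneway` dialect honoured).
How roads and rivers couple is genuinely open — ferry lines are one
possibility but are not systematically tagged — so the package makes the
linkage explicit and conservative: a symmetric *walking connector* from
each road node to its nearest river node within 500 m (configurable),
weighted at 5 km/h walking speed, with the connector count logged on
construction and a warning when none exists. Shortest times are Dijkstra
over the weighted digraph (igraph); the test suite cross-checks them
against exhaustive simple-path enumeration on small random networks, and
verifies the triangle inequality and combined-mode dominance properties.
Scenario graphs (roads / rivers / combined) are rebuilt independently
rather than masked, so scenarios cannot leak state into each other.

## Catchment areas and the scenario comparison

A facility is snapped to the nearest graph node within `max_snap_m`
(default 2,000 m); facilities beyond that distance get no catchment, which
is exactly how a real facility census can exceed the number of catchments.
From the snapped node, single-source shortest times define the reached
edge set at threshold `threshold_h`: an edge is fully reached when both
endpoints are within the threshold, and partially reached with fraction
`(threshold − entry time) / edge time` otherwise, clipping the frontier
edge proportionally by arc length.

* **Threshold.** There is no default: the travel-time limit defines the
  analysis and must be chosen explicitly (the bundled examples use 2 h).
* **Polygon construction.** The catchment polygon is the union of
  constant-width buffers (default 250 m) around the reached edge
  geometries, kept as per-leg rings without dissolving. A convex or alpha
  hull would overclaim coverage across terrain the network never reaches;
  a buffered edge union claims only what is actually reachable. Polygon
  containment (used for the nesting property) is tested at ring vertices
  after a 1 % contraction toward the ring centroid, so shared buffer
  boundaries between nested catchments cannot flip the test.
* **Coverage gain.** `pct_increase = 100 (n_combined − n_roads) / n_roads`.
  With a published triple of roads/rivers/combined counts this denominator
  choice is not unambiguous; the package fixes one explicit, reproducible
  definition. When `n_roads = 0` the gain is reported as `NA`.

`compare_scenarios` runs all facilities under the three scenarios and the
invariants `n_combined ≥ max(n_roads, n_rivers)` and
`|newly_covered| = n_combined − n_roads` (when combined coverage contains
roads coverage) are enforced across seeded fixtures in the tests.

## What the synthetic fixtures emulate — and what they do not

`generate_river_tree` grows a rooted dendritic tree upstream from one
outlet: each new segment attaches exactly at an existing upstream endpoint,
forming a confluence with probability `branch_prob`; discharge accumulates
downstream (each segment adds a jittered headwater contribution of about
5 m³/s to the sum of its children, so a parent always exceeds each child);
flow-regime classes are drawn with probabilities 0.05 / 0.86 / 0.09
(low / medium / high), the class shares observed across Amazon-basin
reaches. The default bounding box is a ~110 km near-equatorial square, so
geodesic and planar distances agree closely and hand-checks are simple.
`generate_road_grid` builds a lattice offset east of the river box beyond
snapping range, creating genuinely river-only territory, and
`generate_facilities` places facilities on road nodes, on river nodes far
from any road, and beyond snapping range of everything, with ground-truth
labels. Each generator draws from its own explicitly seeded stream
(`withr::with_seed`), so fixtures cited in tests are byte-reproducible and
never perturb the ambient RNG.

What passing these tests shows: the topology, attribute, routing and
catchment machinery is correct on networks whose ground truth is known by
construction. What it does not show: fidelity to real hydrography quirks —
braided channels (multiple downstream neighbours), endpoint jitter beyond
1 m, digitization reversals, disconnected basins crossing the study box —
nor hydrological realism of meanders or discharge regimes. Real layers
should be run through `validate_river_layer` and `validate_topology` and
the diagnostic report inspected before routing.

## Problem sizes used in verification

The package verifies itself on synthetic trees of 10–1,000 segments across
100 seeds for the topology invariants, 50 random directed networks of at
most 10 nodes against exhaustive path enumeration for routing, 20 seeded
archipelago fixtures for scenario dominance, 100 write/read round-trips,
and a 10,000-segment tree for the flow-regime shares. These sizes give the
properties room to fail (deep trees, multiple confluence orders, Inf-time
pairs) while keeping the full suite fast enough to run on every change.

## Known limitations

* Travel times are static: no seasonal water-level variation, timetabled
  ferries, or congestion. The flow-regime class is carried so downstream
  users can model dry-season navigability, but the package does not.
* One boat profile for the whole network; no vessel-specific speed or
  draft models, and no fuel or monetary cost.
* Braided (multi-downstream) topology is out of scope; the downstream
  relation must be a forest.
* Geometry I/O is GeoJSON/CSV; the attribute schema is kept DBF-legal so
  the records drop directly into a shapefile attribute table produced by
  standard GIS tooling.
* The per-leg buffered catchment polygons overlap rather than dissolve;
  area sums over rings would double-count and should be computed after a
  dissolve in a GIS if needed.
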