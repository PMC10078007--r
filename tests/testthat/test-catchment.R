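# Facility snapping, service areas, and the three-scenario comparison.

test_that("facilities snap to the nearest node within tolerance only", {
  y <- fixture_scenario("y-network")
  j <- build_junctions(y)
  g <- build_graph(river_records = to_osm_records(y, j))
  conf <- j$nodes[j$nodes$degree == 3, ]
  hit <- snap_facility(g, conf$lon, conf$lat, max_snap_m = 2000)
  expect_equal(hit$distance_m, 0, tolerance = 1e-6)
  expect_equal(hit$node_id, paste0("R", conf$node_id))
  # ~10 km away with a 1 km tolerance: no snap
  expect_null(snap_facility(g, conf$lon + 0.09, conf$lat, max_snap_m = 1000))
})

test_that("service area clips the frontier edge proportionally", {
  # chain of 4 one-hour edges (zero stream), threshold 2.5 h
  tab <- stream_speed_table(c("0" = 0))
  lat <- seq(-2.5, by = -18.52 / 111.32, length.out = 5)
  chain <- river_layer(1:4, c(2:4, 0L),
                       lapply(1:4, function(i) rbind(c(-60, lat[i]),
                                                     c(-60, lat[i + 1]))),
                       length_km = rep(18.52, 4),
                       stream_speed_class = 0L)
  rec <- to_osm_records(chain, build_junctions(chain), table = tab)
  expect_equal(rec$tt_down_h, rep(1, 4))
  g <- build_graph(river_records = rec)
  fac <- facility_layer("f1", -60, lat[1])
  res <- service_area(g, fac, threshold_h = 2.5)
  expect_true(res$has_catchment)
  # per segment (max over the two directions): two full edges, half of the
  # third, none of the fourth
  frac <- tapply(res$reached_edges$fraction, res$reached_edges$ref_id, max)
  expect_equal(as.vector(frac[as.character(1:3)]), c(1, 1, 0.5))
  expect_false("4" %in% names(frac))

  # threshold far below the cheapest incident edge: only a sliver of the
  # first edges is reached, so the polygon collapses to the node's buffer
  tiny <- service_area(g, fac, threshold_h = 1e-6)
  expect_true(tiny$has_catchment)
  expect_lt(max(tiny$reached_edges$fraction), 0.01)
  expect_gt(length(tiny$polygon), 0)

  # unsnapped facility yields an empty result
  far <- facility_layer("f2", -59, -2.5)
  none <- service_area(g, far, threshold_h = 2.5)
  expect_false(none$has_catchment)
  expect_length(none$polygon, 0)
})

test_that("catchment polygons nest under increasing thresholds", {
  for (seed in c(2, 6)) {
    tr <- generate_river_tree(fixture_spec(seed = seed, n_segments = 40))
    rec <- to_osm_records(tr, build_junctions(tr))
    g <- build_graph(river_records = rec)
    out <- g$nodes[1, ]
    fac <- facility_layer("f", out$lon, out$lat)
    polys <- lapply(c(1, 2, 4), function(th)
      service_area(g, fac, threshold_h = th))
    expect_true(catchment_contains(polys[[2]], polys[[1]]))
    expect_true(catchment_contains(polys[[3]], polys[[2]]))
    # reached-edge sets nest too
    key <- function(r) paste(r$reached_edges$from, r$reached_edges$to)
    expect_true(all(key(polys[[1]]) %in% key(polys[[2]])))
    expect_true(all(key(polys[[2]]) %in% key(polys[[3]])))
  }
})

test_that("scenario comparison recovers the archipelago ground truth", {
  fx <- fixture_scenario("archipelago", seed = 1)
  rec <- to_osm_records(fx$rivers, build_junctions(fx$rivers))
  cmp <- compare_scenarios(rec, fx$roads, fx$facilities, threshold_h = 2)
  expect_equal(cmp$summary$n_roads, 6)
  expect_equal(cmp$summary$n_rivers, 3)
  expect_equal(cmp$summary$n_combined, 9)
  expect_length(cmp$newly_covered, 3)
  expect_equal(cmp$pct_increase, 100 * (9 - 6) / 6)
  # per-facility outcomes match the generator's ground-truth labels
  lab <- fx$facilities$expected[match(cmp$per_facility$facility_id,
                                      fx$facilities$facility_id)]
  expect_equal(cmp$per_facility$roads, lab == "road")
  expect_equal(cmp$per_facility$rivers, lab == "river")
  expect_equal(cmp$per_facility$combined, lab != "off")
})

test_that("degenerate comparisons are reported, not errors", {
  fx <- fixture_scenario("archipelago", seed = 2)
  rec <- to_osm_records(fx$rivers, build_junctions(fx$rivers))
  off <- facility_layer("x", fx$spec$bbox[1] - 2, fx$spec$bbox[2] - 2)

  # all facilities off-network: zero counts, undefined increase
  cmp <- compare_scenarios(rec, fx$roads, off, threshold_h = 2)
  expect_equal(cmp$summary$n_roads, 0)
  expect_equal(cmp$summary$n_combined, 0)
  expect_true(is.na(cmp$pct_increase))

  # rivers layer empty: combined reduces to roads
  cmp2 <- compare_scenarios(NULL, fx$roads, fx$facilities, threshold_h = 2)
  expect_null(cmp2$summary$n_combined)
  expect_equal(cmp2$summary$n_roads, 6)
  expect_error(compare_scenarios(rec, fx$roads, fx$facilities), "threshold")
})

test_that("coverage outputs are written to disk", {
  fx <- fixture_scenario("archipelago", seed = 1)
  rec <- to_osm_records(fx$rivers, build_junctions(fx$rivers))
  cmp <- compare_scenarios(rec, fx$roads, fx$facilities, threshold_h = 2)
  gpath <- withr::local_tempfile(fileext = ".geojson")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_catchment_polygons(cmp, gpath)
  write_coverage_table(cmp, cpath)
  fc <- jsonlite::fromJSON(gpath, simplifyVector = FALSE)
  expect_equal(fc$type, "FeatureCollection")
  expect_gt(length(fc$features), 0)
  tab <- read.csv(cpath)
  expect_equal(nrow(tab), 10)
  expect_true(all(c("roads", "rivers", "combined") %in% names(tab)))
})
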