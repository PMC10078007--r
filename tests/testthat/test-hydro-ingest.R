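# Layer I/O: validation totality and write-then-read identity.

test_that("river layer validation rejects malformed inputs, naming offenders", {
  y <- fixture_scenario("y-network")

  bad <- y; bad$next_down[2] <- 99L
  expect_error(validate_river_layer(bad), "dangling.*99")

  bad <- y; bad$seg_id[2] <- 1L
  expect_error(validate_river_layer(bad), "duplicate seg_id")

  bad <- y; bad$next_down <- c(2L, 1L, 1L)  # 1 <-> 2 loop
  expect_error(validate_river_layer(bad), "cycle")

  bad <- y; bad$geometry[[3]] <- bad$geometry[[3]][1, , drop = FALSE]
  expect_error(validate_river_layer(bad), "geometry.*3")

  bad <- y; bad$length_km[1] <- 0
  expect_error(validate_river_layer(bad), "length_km.*1")

  bad <- y; bad$discharge_avg[2] <- -1
  expect_error(validate_river_layer(bad), "discharge_avg.*2")

  expect_error(river_layer(1L, 1L, list(rbind(c(0, 0), c(0, 1)))),
               "itself")
})

test_that("Y-network fixture reads back with one outlet", {
  path <- withr::local_tempfile(fileext = ".geojson")
  write_river_layer(fixture_scenario("y-network"), path)
  rivers <- read_river_layer(path)
  expect_s3_class(rivers, "river_layer")
  expect_equal(nrow(rivers), 3)
  expect_equal(rivers$seg_id[rivers$next_down == 0], 1L)
})

test_that("river and road layers round-trip within coordinate precision", {
  for (seed in c(2, 11, 42)) {
    rivers <- generate_river_tree(fixture_spec(seed = seed, n_segments = 20))
    path <- withr::local_tempfile(fileext = ".geojson")
    write_river_layer(rivers, path)
    back <- read_river_layer(path)
    expect_equal(back$seg_id, rivers$seg_id)
    expect_equal(back$next_down, rivers$next_down)
    expect_equal(back$length_km, rivers$length_km, tolerance = 1e-5)
    expect_equal(back$discharge_avg, rivers$discharge_avg, tolerance = 1e-5)
    expect_equal(back$flow_regime_class, rivers$flow_regime_class)
    for (i in seq_len(nrow(rivers)))
      expect_lt(max(abs(back$geometry[[i]] - rivers$geometry[[i]])), 1e-6)

    roads <- generate_road_grid(fixture_spec(seed = seed))
    rpath <- withr::local_tempfile(fileext = ".geojson")
    write_roads_layer(roads, rpath)
    rback <- read_roads_layer(rpath)
    expect_equal(rback$osm_id, roads$osm_id)
    expect_equal(rback$oneway, roads$oneway)
    expect_equal(rback$maxspeed_kmh, roads$maxspeed_kmh)
    expect_equal(rback$length_km, roads$length_km, tolerance = 1e-5)
  }
})

test_that("oneway dialects are normalized on read and honoured in the graph", {
  expect_equal(decode_oneway(c("B", "no", "", "yes", "F", "-1", "T")),
               c("B", "B", "B", "F", "F", "T", "T"))
  expect_error(decode_oneway("maybe"), "unrecognized")

  # a forward-only edge contributes no reverse traversal
  g2 <- rbind(c(-60, -3), c(-60, -2.99))
  roads <- road_layer("a", geometry = list(g2), oneway = "yes",
                      maxspeed_kmh = 40)
  graph <- build_graph(road_edges = roads)
  expect_equal(nrow(graph$edges), 1)
  a <- node_at(graph, g2[1, ]); b <- node_at(graph, g2[2, ])
  expect_true(is.finite(shortest_time(graph, a, b)))
  expect_identical(shortest_time(graph, b, a), Inf)
})

test_that("facility CSV round-trips and rejects bad coordinates", {
  fac <- facility_layer(c("a", "b"), c(-60, -59.5), c(-3, -2.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_facilities(fac, path)
  back <- read_facilities(path)
  expect_equal(as.data.frame(back), as.data.frame(fac))
  expect_error(facility_layer(c("a", "a"), c(0, 0), c(0, 0)), "duplicate")
  expect_error(facility_layer("a", 500, 0), "coordinates")
})

test_that("routable layer: empty schema, travel-time identity, round-trip", {
  # DBF name map is collision-free and <= 10 chars
  map <- routable_field_names()
  expect_false(anyDuplicated(unname(map)) > 0)
  expect_true(all(nchar(map) <= 10))

  y <- fixture_scenario("y-network")
  rec <- to_osm_records(y, build_junctions(y))

  # empty collection -> valid empty layer with full schema
  epath <- withr::local_tempfile(fileext = ".geojson")
  write_routable_layer(rec[0, ], epath)
  empty <- read_routable_layer(epath)
  expect_equal(nrow(empty), 0)
  expect_true(all(names(map) %in% names(empty)))

  # 18.52 km at 18.52 km/h (zero stream) stores a 1.0 h travel time
  one <- rec[1, ]
  one$length_km <- 18.52
  one$stream_speed_kmh <- 0
  one$tt_down_h <- one$tt_up_h <- 18.52 / 18.52
  p1 <- withr::local_tempfile(fileext = ".geojson")
  write_routable_layer(one, p1)
  expect_equal(read_routable_layer(p1)$tt_down_h, 1.0)

  # generator output round-trips attribute-for-attribute
  tr <- generate_river_tree(fixture_spec(seed = 5, n_segments = 50))
  rec <- to_osm_records(tr, build_junctions(tr), min_discharge_cms = 8)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_routable_layer(rec, path)
  back <- read_routable_layer(path)
  for (nm in setdiff(names(routable_field_names()),
                     c("geometry"))) {
    if (is.numeric(rec[[nm]]))
      expect_equal(back[[nm]], rec[[nm]], tolerance = 1e-5,
                   label = paste("field", nm))
    else expect_equal(back[[nm]], rec[[nm]], label = paste("field", nm))
  }
})
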