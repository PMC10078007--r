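# Boat speeds, per-direction travel times, regime classes, navigability,
# and OSM record emission.

test_that("effective speed is boat plus/minus stream, floored upstream", {
  p <- boat_profile()
  expect_equal(p$avg_speed_kmh, 18.52)
  expect_equal(p$max_speed_kmh, 37)
  expect_equal(effective_speed(p, 0, "downstream"), 18.52)
  expect_equal(effective_speed(p, 0, "upstream"), 18.52)
  expect_equal(effective_speed(p, 3, "downstream"), 21.52)
  expect_equal(effective_speed(p, 3, "upstream"), 15.52)
  expect_equal(effective_speed(p, 20, "upstream"), 1.0)  # floor clamp
  expect_error(effective_speed(p, -1, "downstream"), ">= 0")
  expect_error(boat_profile(avg_speed_kmh = 50, max_speed_kmh = 37))
})

test_that("travel times are length over effective speed, per direction", {
  tab <- stream_speed_table(c("0" = 0, "1" = 3))
  r0 <- river_layer(1L, 0L, list(rbind(c(-60, -3), c(-60, -2.9))),
                    length_km = 18.52, stream_speed_class = 0L)
  tt <- segment_travel_times(r0, table = tab)
  expect_equal(tt$tt_down_h, 1.0)
  expect_equal(tt$tt_up_h, 1.0)

  r1 <- river_layer(1L, 0L, list(rbind(c(-60, -3), c(-60, -2.9))),
                    length_km = 21.52, stream_speed_class = 1L)
  tt <- segment_travel_times(r1, table = tab)
  expect_equal(tt$tt_down_h, 1.0)           # 21.52 / (18.52 + 3)
  expect_equal(tt$tt_up_h, 21.52 / 15.52)

  r9 <- river_layer(1L, 0L, list(rbind(c(-60, -3), c(-60, -2.9))),
                    stream_speed_class = 9L)
  expect_error(segment_travel_times(r9, table = stream_speed_table()),
               "unmapped")
})

test_that("downstream dominance holds over generator output", {
  tr <- generate_river_tree(fixture_spec(seed = 12, n_segments = 100))
  tt <- segment_travel_times(tr)
  pos <- tt$stream_kmh > 0
  expect_true(any(pos))
  expect_true(all(tt$tt_down_h[pos] < tt$tt_up_h[pos]))
  expect_true(all(tt$tt_down_h[!pos] == tt$tt_up_h[!pos]))
  expect_true(all(is.finite(tt$tt_down_h) & tt$tt_down_h > 0))
})

test_that("stream-speed table enforces monotone non-negative values", {
  expect_error(stream_speed_table(c("1" = -1)), ">= 0")
  expect_error(stream_speed_table(c("1" = 2, "2" = 1)), "non-decreasing")
  expect_equal(stream_speed_for_class(stream_speed_table(), c(3, 1)),
               c(3.0, 0.5))
})

test_that("flow regime codes map deterministically and reject unknowns", {
  expect_equal(classify_flow_regime(c("low", 2, "high", 1)),
               c("low", "medium", "high", "low"))
  expect_error(classify_flow_regime("glacial"), "glacial")
})

test_that("sampled regime shares match their generating probabilities", {
  spec <- fixture_spec(seed = 31, n_segments = 10000)
  draws <- withr::with_seed(spec$seed,
    sample(names(spec$regime_probs), spec$n_segments, replace = TRUE,
           prob = spec$regime_probs))
  shares <- table(classify_flow_regime(draws)) / length(draws)
  expect_lt(abs(shares[["low"]] - 0.05), 0.01)
  expect_lt(abs(shares[["medium"]] - 0.86), 0.01)
  expect_lt(abs(shares[["high"]] - 0.09), 0.01)
})

test_that("navigability flags by discharge and is monotone in the threshold", {
  r <- river_chain(n = 3)
  r$discharge_avg <- c(1, 5, 10)
  expect_equal(sum(navigability_filter(r, 0)$navigable), 3)
  expect_equal(sum(navigability_filter(r, 5)$navigable), 2)
  expect_error(navigability_filter(r, -1), ">= 0")

  tr <- generate_river_tree(fixture_spec(seed = 8, n_segments = 80))
  counts <- vapply(c(0, 2, 5, 10, 20, 50, 1e6), function(th)
    sum(navigability_filter(tr, th)$navigable), numeric(1))
  expect_equal(counts[1], 80)       # threshold 0: everything navigable
  expect_true(all(diff(counts) <= 0))
  # segments below threshold are kept, only flagged
  expect_equal(nrow(navigability_filter(tr, 1e6)), 80)
})

test_that("emitted OSM records honour the schema and its sentinels", {
  y <- fixture_scenario("y-network")
  rec <- to_osm_records(y, build_junctions(y))
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$bridge == "do not apply"))
  expect_true(all(rec$tunnel == "do not apply"))
  expect_true(all(rec$lanes == "do not apply"))
  expect_true(all(rec$electricity == "do not apply"))
  expect_true(all(rec$width_limit == "unrestricted"))
  expect_true(all(rec$oneway == "B"))
  expect_false(any(rec$foot_access))
  expect_true(all(rec$avgspeed_kmh == 18.52))
  expect_true(all(rec$maxspeed_kmh == 37))
  # travel-time consistency: re-derivable from the stored fields
  expect_equal(rec$tt_down_h,
               rec$length_km / (rec$avgspeed_kmh + rec$stream_speed_kmh))
  expect_equal(rec$tt_up_h,
               rec$length_km / pmax(rec$avgspeed_kmh - rec$stream_speed_kmh,
                                    1))
  # no nulls outside sanctioned sentinels
  expect_false(anyNA(as.data.frame(rec)[, names(routable_field_names())]))

  # record count equals segment count across seeds
  for (seed in 1:10) {
    tr <- generate_river_tree(fixture_spec(seed = seed, n_segments = 30))
    expect_equal(nrow(to_osm_records(tr, build_junctions(tr))), 30)
  }
})
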