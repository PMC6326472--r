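test_that("landscape generation is deterministic and validates extent", {
  l1 <- generate_landscape(seed = 3)
  l2 <- generate_landscape(seed = 3)
  f1 <- tempfile(fileext = ".geojson")
  f2 <- tempfile(fileext = ".geojson")
  write_landscape_geojson(l1, f1)
  write_landscape_geojson(l2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(l1$veg, generate_landscape(seed = 4)$veg))
  expect_error(generate_landscape(landscape_config(extent_km = 20)),
               "32 km")
})

test_that("no forest means the nearest-forest cap everywhere", {
  land <- make_test_landscape(width = 300)
  pts <- riversel:::sample_inchannel(land, 1000, 30000, 50, seed = 9)
  expect_equal(measure_nf(land, pts[, "s"], pts[, "t"]), rep(400, 50))
})

test_that("sampled unobstructed widths bracket the configured range", {
  # Monte-Carlo check against the generator's own width profile; the
  # configured 10th-90th percentile range is c(50, 450)
  land <- generate_landscape(seed = 2)
  pts <- riversel:::sample_inchannel(land, 0, land$extent_m, 1000, seed = 5)
  met <- measure_widths(land, pts[, "s"], pts[, "t"])
  q <- unname(stats::quantile(met$uocw, c(0.1, 0.9)))
  rng <- land$config$uocw_range
  expect_lte(q[1], rng[1])
  expect_gte(q[2], rng[2])
})

test_that("null-effect truth selects alternatives uniformly", {
  # scaled down from the 5,000-set example to 1,500 sets for runtime
  land <- small_landscape(7)
  spec <- selection_spec(uocw_beta = 0, nf_beta = 0, n_use = 1500)
  ch <- simulate_stopovers(land, spec, seed = 11)
  used_idx <- ch$alt_id[ch$used == 1]
  expect_length(used_idx, 1500)
  expect_gt(stats::chisq.test(tabulate(used_idx, 21))$p.value, 0.01)
})

test_that("strong selection shifts used points toward the drivers", {
  land <- small_landscape(8)
  spec <- selection_spec(n_use = 300)  # default strong UOCW + NF truth
  ch <- simulate_stopovers(land, spec, seed = 13)
  expect_gt(mean(ch$uocw_m[ch$used == 1]), mean(ch$uocw_m[ch$used == 0]))
  expect_gt(mean(ch$nf_m[ch$used == 1]), mean(ch$nf_m[ch$used == 0]))
})

test_that("simulated choice sets have the stated bookkeeping", {
  land <- small_landscape(1)
  ch <- simulate_stopovers(land, selection_spec(n_use = 85), seed = 2)
  expect_equal(sum(ch$used == 1), 85)
  expect_equal(sum(ch$used == 0), 1700)
  expect_true(all(tapply(ch$used, ch$set_id, sum) == 1))
  # determinism of the full simulation
  ch2 <- simulate_stopovers(land, selection_spec(n_use = 85), seed = 2)
  expect_identical(ch, ch2)
  # every alternative lies inside its window
  anchors <- attr(ch, "anchors")
  off <- abs(ch$x_m - anchors[ch$set_id])
  expect_lte(max(off), 16000)
})
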