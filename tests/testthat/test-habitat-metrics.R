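test_that("widths in an unobstructed rectangular channel are exact", {
  land <- make_test_landscape(width = 200)
  w <- measure_widths(land, 5000, 0)
  expect_equal(unlist(w), c(uocw = 200, tcw = 200, ufcw = 200))
  expect_error(measure_widths(land, 5000, 150), "outside the channel")
})

test_that("a dense island segments the transect at the point's portion", {
  # 200 m channel, 40 m island from t = -40 to 0: upper portion 100 m,
  # lower portion 60 m
  veg <- data.frame(s0 = 4000, s1 = 6000, t0 = -40, t1 = 0)
  land <- make_test_landscape(width = 200, veg = veg)
  up <- measure_widths(land, 5000, 50)
  expect_equal(unlist(up), c(uocw = 100, tcw = 200, ufcw = 200))
  low <- measure_widths(land, 5000, -70)
  expect_equal(unlist(low), c(uocw = 60, tcw = 200, ufcw = 200))
  expect_error(measure_widths(land, 5000, -20), "vegetated island")
  # outside the island's reach the channel is unobstructed
  expect_equal(measure_widths(land, 7000, 50)$uocw, 200)
})

test_that("widths match the raster-counting oracle on random landscapes", {
  land <- generate_landscape(seed = 6)
  pts <- riversel:::sample_inchannel(land, 0, land$extent_m, 50, seed = 21)
  met <- measure_widths(land, pts[, "s"], pts[, "t"])
  for (i in seq_len(50)) {
    o <- oracle_widths(land, pts[i, "s"], pts[i, "t"])
    expect_lt(abs(met$uocw[i] - o["uocw"]), 0.5)
    expect_lt(abs(met$tcw[i] - o["tcw"]), 0.5)
    expect_lt(abs(met$ufcw[i] - o["ufcw"]), 0.5)
  }
})

test_that("nearest-forest distance is truncated, zero on contact, exact", {
  # forest 500 m from the channel edge: beyond the 400 m cap
  far <- data.frame(s0 = 4000, s1 = 6000, t0 = 600, t1 = 800)
  land <- make_test_landscape(width = 200, forest = far)
  expect_equal(measure_nf(land, 5000, 0), 400)
  # touching the point: distance zero (patch corner at the point)
  near <- data.frame(s0 = 5000, s1 = 6000, t0 = 0, t1 = 300)
  land2 <- make_test_landscape(width = 200, forest = near)
  expect_equal(measure_nf(land2, 5000, 0), 0)
  # parallel-offset case: inner edge 80 m above the point
  expect_equal(measure_nf(land2, 5500, -80), 80)
})

test_that("nearest forest matches the boundary-sampling oracle", {
  land <- generate_landscape(seed = 7)
  pts <- riversel:::sample_inchannel(land, 0, land$extent_m, 50, seed = 22)
  nf <- measure_nf(land, pts[, "s"], pts[, "t"])
  for (i in seq_len(50)) {
    expect_lt(abs(nf[i] - oracle_nf(land, pts[i, "s"], pts[i, "t"])), 0.5)
  }
})

test_that("nearest forest shrinks as a patch moves closer", {
  d <- vapply(seq(600, 150, by = -50), function(t0) {
    land <- make_test_landscape(
      width = 200, forest = data.frame(s0 = 4000, s1 = 6000,
                                       t0 = t0, t1 = t0 + 100))
    measure_nf(land, 5000, 0)
  }, numeric(1))
  expect_true(all(diff(d) <= 0))
  expect_equal(d[1], 400)  # truncated when too far
})

test_that("flow metrics follow their definitions", {
  expect_equal(unlist(flow_metrics(10, 100, 200)), c(ud = 0.1, dis = 0.05))
  expect_equal(unlist(flow_metrics(0, 50, 100)), c(ud = 0, dis = 0))
  fm <- flow_metrics(7.3, 146, 365)
  expect_equal(round(unlist(fm), 2), c(ud = 0.05, dis = 0.02))
  expect_error(flow_metrics(10, 0, 100), "positive")
  expect_error(flow_metrics(-1, 50, 100), "non-negative")
})

test_that("width ordering and NF bounds hold across a seeded landscape", {
  land <- generate_landscape(seed = 9)
  pts <- riversel:::sample_inchannel(land, 0, land$extent_m, 1000,
                                     seed = 23)
  met <- attach_metrics(land, pts[, "s"], pts[, "t"], 40)
  expect_true(all(met$uocw_m > 0))
  expect_true(all(met$uocw_m <= met$ufcw_m + 1e-9))
  expect_true(all(met$ufcw_m <= met$tcw_m + 1e-9))
  expect_true(all(met$nf_m >= 0 & met$nf_m <= 400))
  expect_true(all(met$ud_cms_per_m >= met$dis_cms_per_m))
})
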