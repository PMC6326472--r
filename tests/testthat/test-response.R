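test_that("null model gives a flat ratio with zero-width intervals", {
  df <- random_choice_data(30, 5, seed = 81)
  f <- fit_dcgam(df, candidate_model("NULL"))
  rf <- response_function(f, "UOCW", df)
  expect_true(all(rf$ratio == 1))
  expect_true(all(rf$ci_high - rf$ci_low == 0))
  pp <- peak_and_plateau(rf)
  expect_equal(unname(pp["plateau_low"]), min(rf$grid))  # flat: whole grid
})

test_that("a positive linear term yields a strictly increasing ratio", {
  land <- small_landscape(21)
  sp <- selection_spec(n_use = 120, uocw_beta = 4, uocw_plateau = 900,
                       nf_beta = 0)
  ch <- simulate_stopovers(land, sp, seed = 22)
  f <- fit_dcgam(ch, candidate_model("UOCW", "UOCW", smooth = FALSE))
  expect_gt(f$coefficients, 0)
  rf <- response_function(f, "UOCW", ch)
  expect_true(all(diff(rf$ratio) > 0))
  expect_equal(max(rf$ratio), 1)
  expect_equal(rf$ratio[length(rf$ratio)], 1)
  expect_true(all(rf$ci_low <= rf$ratio & rf$ratio <= rf$ci_high))
  # tight increasing intervals push the plateau onset near the grid top
  pp <- peak_and_plateau(rf)
  expect_gt(unname(pp["plateau_low"]),
            stats::quantile(rf$grid, 0.5, names = FALSE))
  expect_error(response_function(f, "NF", ch), "not a term")
})

test_that("scaling is idempotent and respects the max_upper variant", {
  land <- small_landscape(23)
  ch <- simulate_stopovers(land, selection_spec(n_use = 100), seed = 24)
  f <- fit_dcgam(ch, candidate_model("UOCW", "UOCW"))
  rf <- response_function(f, "UOCW", ch)
  expect_equal(max(rf$ratio), 1)
  # rescaling the already scaled ratio changes nothing
  expect_equal(rf$ratio / max(rf$ratio), rf$ratio)
  up <- response_function(f, "UOCW", ch, scale = "max_upper")
  expect_equal(max(up$ci_high), 1)
  expect_lte(max(up$ratio), 1)
})

test_that("pointwise intervals cover the true ratio at the stated rate", {
  # simulate from a known linear truth, fit the matching model and check
  # 90% interval coverage at the grid midpoint over 100 replicates
  m <- candidate_model("UOCW", "UOCW", smooth = FALSE)
  slope_true <- 4 / 900
  covered <- vapply(1:100, function(r) {
    land <- generate_landscape(landscape_config(extent_km = 50),
                               derive_seed(r, "cl"))
    sp <- selection_spec(n_use = 100, uocw_beta = 4, uocw_plateau = 900,
                         nf_beta = 0)
    ch <- simulate_stopovers(land, sp, seed = derive_seed(r, "cs"))
    f <- fit_dcgam(ch, m)
    rf <- response_function(f, "UOCW", ch)
    mid <- 50
    truth <- exp(slope_true * (rf$grid[mid] -
                                 rf$grid[which.max(rf$ratio)]))
    rf$ci_low[mid] <= truth && truth <= rf$ci_high[mid]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 0.95)
})
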