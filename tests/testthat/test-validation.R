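test_that("each replicate conserves expected and observed use totals", {
  land <- small_landscape(31)
  ch <- simulate_stopovers(land, selection_spec(n_use = 90), seed = 32)
  m <- candidate_model("UOCW+NF", c("UOCW", "NF"))
  sl <- calibration_rep(ch, m, seed = 5, lambda = c(UOCW = 1, NF = 1))
  n_use_test <- 90 - round(90 * 2 / 3)
  expect_equal(sum(attr(sl, "expected")), n_use_test, tolerance = 1e-9)
  expect_equal(sum(attr(sl, "observed")), n_use_test)
  expect_length(attr(sl, "expected"), 20)
  # deterministic given the seed
  sl2 <- calibration_rep(ch, m, seed = 5, lambda = c(UOCW = 1, NF = 1))
  expect_equal(as.numeric(sl), as.numeric(sl2))
})

test_that("degenerate (tied) predictions are skipped and then error out", {
  land <- small_landscape(33)
  ch <- simulate_stopovers(land, selection_spec(n_use = 30), seed = 34)
  # the null model predicts identically everywhere: every bin break ties
  expect_true(is.na(calibration_rep(ch, candidate_model("NULL"),
                                    seed = 1)))
  expect_error(validate_model(ch, candidate_model("NULL"), n_reps = 10,
                              seed = 2),
               "degenerate")
})

test_that("a single replicate collapses the interval to its slope", {
  land <- small_landscape(35)
  ch <- simulate_stopovers(land, selection_spec(n_use = 60), seed = 36)
  v <- validate_model(ch, candidate_model("UOCW", "UOCW"), n_reps = 1,
                      seed = 3)
  expect_equal(v$ci95[1], v$ci95[2])
  expect_equal(v$ci95[1], v$mean_slope)
})

test_that("classify_fit reproduces the published verdicts", {
  expect_equal(classify_fit(c(0.607, 1.182)), "Good")
  expect_equal(classify_fit(c(0.039, 0.900)), "Adequate")
  expect_equal(classify_fit(c(-0.2, 0.5)), "Poor")
})

test_that("the three verdicts partition every interval", {
  withr::with_seed(99, {
    for (i in 1:200) {
      lo <- runif(1, -2, 2)
      hi <- lo + runif(1, 0, 3)
      v <- classify_fit(c(lo, hi))
      expect_true(v %in% c("Good", "Adequate", "Poor"))
      if (lo <= 0 && 0 <= hi) {
        expect_equal(v, "Poor")  # spanning zero wins, even if 1 is inside
      } else if (lo <= 1 && 1 <= hi) {
        expect_equal(v, "Good")
      } else {
        expect_equal(v, "Adequate")
      }
    }
  })
  expect_error(classify_fit(c(2, 1)))
})
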