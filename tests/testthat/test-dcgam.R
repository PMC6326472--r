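test_that("spline basis: partition of unity, penalty rank, node capacity", {
  x <- runif(200, 0, 500)
  b <- spline_basis(x, 4)
  expect_equal(rowSums(b$raw), rep(1, 200), tolerance = 1e-12)
  expect_equal(qr(b$penalty_raw)$rank, 2)       # order-2 penalty, dim 4
  expect_equal(ncol(b$design), 3)
  expect_equal(unname(colMeans(b$design)), rep(0, 3), tolerance = 1e-12)
  # with data at the nodes and no penalty, any node values -- here a
  # quadratic -- are reproduced exactly
  xn <- b$knots
  yn <- 2 + 0.5 * xn - 0.001 * xn^2
  bn <- spline_basis(xn, 4, range = range(x))
  fit <- lm(yn ~ bn$design)
  expect_equal(unname(fitted(fit)), yn, tolerance = 1e-6)
  expect_error(spline_basis(c(x, 600), 4, range = c(0, 500)), "outside")
  expect_warning(spline_eval(b, c(-10, 600)), "clamped")
})

test_that("conditional log-likelihood: symmetry, arithmetic, oracle", {
  # all alternatives identical: every set contributes -ln(21)
  df <- random_choice_data(10, 21, seed = 51)
  eta <- rep(0, nrow(df))
  expect_equal(conditional_loglik(eta, df$set_id, df$used),
               -10 * log(21))
  # two alternatives, x_used = 1, x_avail = 0, beta = ln 3 -> ln(3/4)
  expect_equal(conditional_loglik(c(log(3), 0), c(1, 1), c(1, 0)),
               log(3 / 4))
  # brute-force oracle on random small sets and coefficients
  for (r in 1:10) {
    df <- random_choice_data(30, 4, seed = 60 + r)
    eta <- withr::with_seed(70 + r,
                            0.002 * df$uocw_m * rnorm(1) +
                              0.003 * df$nf_m * rnorm(1))
    expect_equal(conditional_loglik(eta, df$set_id, df$used),
                 oracle_loglik(eta, df$set_id, df$used),
                 tolerance = 1e-10)
  }
  expect_error(conditional_loglik(c(NA, 0), c(1, 1), c(1, 0)),
               "non-finite")
})

test_that("linear-only fits match the independent conditional-logit MLE", {
  skip_if_not_installed("survival")
  library(survival)
  m <- candidate_model("UOCW+NF", c("UOCW", "NF"),
                       smooth = c(FALSE, FALSE))
  for (r in 1:5) {
    land <- small_landscape(100 + r, extent_km = 36)
    ch <- simulate_stopovers(land, selection_spec(n_use = 40),
                             seed = 200 + r)
    fit <- fit_dcgam(ch, m)
    oracle <- survival::clogit(used ~ uocw_m + nf_m + strata(set_id),
                               data = ch)
    expect_equal(unname(fit$coefficients), unname(coef(oracle)),
                 tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(oracle)),
                 tolerance = 1e-8)
  }
})

test_that("null model likelihood and AIC are forced", {
  df <- random_choice_data(50, 21, seed = 52)
  f <- fit_dcgam(df, candidate_model("NULL"))
  expect_equal(f$loglik, -50 * log(21))
  expect_equal(f$aic, 2 * 50 * log(21))
  expect_equal(f$edf_total, 0)
})

test_that("EDF hits both limits and decreases monotonically in lambda", {
  land <- small_landscape(12)
  ch <- simulate_stopovers(land, selection_spec(n_use = 60), seed = 14)
  m <- candidate_model("UOCW", "UOCW")
  lam_seq <- c(0, 1e-2, 1, 1e2, 1e4, 1e12)
  edf <- vapply(lam_seq, function(l)
    unname(fit_dcgam(ch, m, lambda = c(UOCW = l))$edf["UOCW"]),
    numeric(1))
  expect_equal(edf[1], 3)                # basis_dim - 1 at lambda = 0
  expect_lt(abs(edf[length(edf)] - 1), 0.05)  # straight-line limit
  expect_true(all(diff(edf) < 1e-8))     # monotone non-increasing
})

test_that("likelihood is invariant to within-set constant covariate shifts", {
  land <- small_landscape(13)
  ch <- simulate_stopovers(land, selection_spec(n_use = 50), seed = 15)
  m <- candidate_model("UOCW+NF", c("UOCW", "NF"),
                       smooth = c(TRUE, FALSE))
  f1 <- fit_dcgam(ch, m, lambda = c(UOCW = 5))
  ch2 <- ch
  ch2$uocw_m <- ch2$uocw_m + 123.4   # same shift in every set
  ch2$nf_m <- ch2$nf_m + 77.7
  f2 <- fit_dcgam(ch2, m, lambda = c(UOCW = 5))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("linear-truth data drive the smooth to a line and the fallback", {
  # truth linear in UOCW over its whole range (plateau beyond the data)
  n_trig <- 0
  n_aic <- 0
  reps <- 10  # scaled down from the 100-replicate example for runtime
  for (r in seq_len(reps)) {
    land <- generate_landscape(landscape_config(extent_km = 60),
                               derive_seed(r, "lt-l"))
    sp <- selection_spec(n_use = 150, uocw_beta = 4, uocw_plateau = 900,
                         nf_beta = 0)
    ch <- simulate_stopovers(land, sp, seed = derive_seed(r, "lt-s"))
    f <- fit_dcgam(ch, candidate_model("UOCW", "UOCW"))
    fb <- linear_fallback(f)
    if (fb$terms$UOCW$type == "linear") n_trig <- n_trig + 1
    # near EDF 1 the two fits are the same model; AIC differences are
    # Newton-tolerance noise (~1e-3), so count ties at 0.01 AIC units
    if (fb$aic <= f$aic + 0.01) n_aic <- n_aic + 1
  }
  expect_gte(n_trig, 8)       # EDF ~ 1 triggers the fallback
  expect_gte(n_aic, 9)        # the parametric line is never worse
  # a clearly nonlinear fit is returned unchanged
  land <- small_landscape(14)
  ch <- simulate_stopovers(land, selection_spec(n_use = 120), seed = 16)
  f <- fit_dcgam(ch, candidate_model("UOCW", "UOCW"))
  if (abs(f$edf["UOCW"] - 1) > 0.05) {
    expect_identical(linear_fallback(f), f)
  }
})

test_that("model ranking arithmetic, parsimony rule and errors", {
  # single model: delta 0, weight 1, selected
  df <- random_choice_data(20, 5, seed = 53)
  f <- fit_dcgam(df, candidate_model("NULL"))
  r1 <- rank_models(list(f))
  expect_equal(r1$delta_aic, 0)
  expect_equal(r1$weight, 1)
  expect_true(r1$selected)
  # weights always sum to one; parsimony picks fewest covariates in window
  tab <- data.frame(model = c("A3", "B1", "C2"), aic = c(100, 101.5, 100.9),
                    n_cov = c(3, 1, 2))
  r2 <- rank_models(tab)
  expect_equal(sum(r2$weight), 1, tolerance = 1e-9)
  expect_true(all(r2$delta_aic >= 0))
  expect_equal(attr(r2, "selected_model"), "B1")
  # differing set counts across fits is an error
  f2 <- fit_dcgam(random_choice_data(25, 5, seed = 54),
                  candidate_model("NULL"))
  expect_error(rank_models(list(f, f2)), "differing")
})
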