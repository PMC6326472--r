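#' One calibration replicate: train/test split and binned-use slope
#'
#' Fits the model on a random two-thirds of the choice sets and computes
#' the discrete-choice predicted value of every test location: its
#' within-choice-set selection probability `exp(eta) / sum_set exp(eta)`.
#' The predicted values of the *available* test locations are scaled to
#' sum to the number of test use locations, `n_bins` percentile bins are
#' formed from the scaled available predictions, and expected use (sum of
#' scaled predictions per bin) is compared with actual use (count of test
#' use locations whose own scaled prediction falls in the bin's
#' interval).  The replicate's statistic is the OLS slope (with
#' intercept) of actual on expected use; a well-calibrated model gives
#' slopes near one.
#'
#' @param data a `choice_data` data.frame.
#' @param model a [candidate_model()].
#' @param train_frac training fraction (default 2/3).
#' @param n_bins number of percentile bins (default 20).
#' @param seed integer seed for the partition.
#' @param lambda optional fixed smoothing parameters (e.g. from a
#'   full-data fit) to avoid re-running the smoothness search per
#'   replicate; `NULL` re-estimates smoothness on each training fit.
#' @param basis_dim passed to [fit_dcgam()].
#' @param scramble if `TRUE`, randomly permutes the test predictions among
#'   test locations before binning -- a broken-model control whose slope
#'   should concentrate near zero.
#' @return the slope, or `NA` if the bin structure is degenerate (all
#'   predictions tied), in which case the replicate is to be skipped.
#' @export
calibration_rep <- function(data, model, train_frac = 2 / 3, n_bins = 20,
                            seed = 1L, lambda = NULL, basis_dim = 4,
                            scramble = FALSE) {
  stopifnot(n_bins >= 2)
  parts <- split_train_test(data, train_frac, derive_seed(seed, "split"))
  fit <- fit_dcgam(parts$train, model, basis_dim = basis_dim,
                   lambda = lambda)
  test <- parts$test
  eta <- suppressWarnings(predict(fit, test))
  w <- exp(eta - max(eta))
  gi <- match(test$set_id, unique(test$set_id))
  w <- w / drop(rowsum(w, gi))[gi]  # within-set choice probability
  if (scramble) {
    w <- with_seed(derive_seed(seed, "scramble"), sample(w))
  }
  avail <- test$used == 0
  n_use <- sum(test$used == 1)
  sc <- n_use / sum(w[avail])
  pred_avail <- w[avail] * sc
  pred_use <- w[!avail] * sc
  # percentile breakpoints from the scaled available predictions only;
  # ties broken by a deterministic rank-based jitter before quantiling
  jit <- pred_avail + rank(pred_avail, ties.method = "first") * 1e-12
  brk <- stats::quantile(jit, probs = seq(0, 1, length.out = n_bins + 1),
                         names = FALSE)
  brk[1] <- -Inf
  brk[n_bins + 1] <- Inf
  if (any(diff(brk) <= 0)) return(NA_real_)  # degenerate: ties collapse bins
  bin_avail <- cut(jit, brk, labels = FALSE, right = TRUE)
  bin_use <- cut(pred_use, brk, labels = FALSE, right = TRUE)
  expected <- vapply(seq_len(n_bins),
                     function(b) sum(pred_avail[bin_avail == b]), numeric(1))
  observed <- tabulate(bin_use, nbins = n_bins)
  if (stats::sd(expected) == 0) return(NA_real_)
  structure(unname(stats::coef(stats::lm(observed ~ expected))[2]),
            expected = expected, observed = observed)
}

#' Repeated calibration validation with a Good/Adequate/Poor verdict
#'
#' Runs [calibration_rep()] over `n_reps` independent random partitions,
#' averages the slopes, takes the 2.5/97.5 percentiles of the replicate
#' slopes as the 95% interval, and classifies the fit with
#' [classify_fit()].  By default the smoothing parameters are estimated
#' once on the full data and held fixed across replicates (structure and
#' smoothness are treated as given; only coefficients are re-estimated per
#' training partition), which keeps a thousand replicates tractable.
#'
#' @inheritParams calibration_rep
#' @param n_reps number of replicates (default 1000).
#' @param refit_lambda if `TRUE`, re-run the smoothness search on every
#'   training partition.
#' @return object of class `validation_result`: `slopes`, `mean_slope`,
#'   `ci95`, `verdict`, `n_reps`, `n_bins`, `n_skipped`, `seed`.
#' @export
validate_model <- function(data, model, n_reps = 1000, train_frac = 2 / 3,
                           n_bins = 20, seed = 1L, basis_dim = 4,
                           refit_lambda = FALSE, scramble = FALSE) {
  lambda <- NULL
  if (!refit_lambda && length(model$covariates)) {
    full <- fit_dcgam(data, model, basis_dim = basis_dim)
    lambda <- full$lambda
  }
  slopes <- vapply(seq_len(n_reps), function(r) {
    calibration_rep(data, model, train_frac, n_bins,
                    seed = derive_seed(seed, "rep", r),
                    lambda = lambda, basis_dim = basis_dim,
                    scramble = scramble)
  }, numeric(1))
  n_skip <- sum(is.na(slopes))
  if (n_skip > 0.2 * n_reps) {
    stop("more than 20% of calibration replicates were degenerate (",
         n_skip, "/", n_reps, "); predictions are effectively tied")
  }
  ok <- slopes[!is.na(slopes)]
  ci <- if (length(ok) > 1) {
    unname(stats::quantile(ok, c(0.025, 0.975)))
  } else c(ok, ok)
  structure(list(slopes = slopes, mean_slope = mean(ok),
                 ci95 = ci, verdict = classify_fit(ci),
                 n_reps = n_reps, n_bins = n_bins,
                 n_skipped = n_skip, seed = seed),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result> ", x$n_reps, " replicates (", x$n_skipped,
      " skipped), ", x$n_bins, " bins\n", sep = "")
  cat("  mean slope ", signif(x$mean_slope, 4), " (95% CI ",
      signif(x$ci95[1], 4), " to ", signif(x$ci95[2], 4), "): ",
      x$verdict, "\n", sep = "")
  invisible(x)
}

#' Classify a calibration-slope confidence interval
#'
#' A Good model's 95% interval contains 1 and not 0; an Adequate model's
#' interval contains neither 0 nor 1; any interval spanning 0 is Poor
#' (including the ambiguous interval containing both 0 and 1, which the
#' spanning-zero clause claims first).
#'
#' @param ci95 numeric length-2 interval (low, high).
#' @return one of "Good", "Adequate", "Poor".
#' @export
classify_fit <- function(ci95) {
  stopifnot(length(ci95) == 2, ci95[1] <= ci95[2])
  contains <- function(v) ci95[1] <= v && v <= ci95[2]
  if (contains(0)) return("Poor")
  if (contains(1)) return("Good")
  "Adequate"
}
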