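#' Relative-selection-ratio response function for one covariate
#'
#' Evaluates the fitted linear predictor over a grid spanning the 10th to
#' 90th percentile of the covariate at *used* locations (extreme values
#' are not displayed), holding every other model term constant at its data
#' mean -- constant terms cancel from the relative selection ratio, which
#' is `exp(eta - max eta)` so its maximum is exactly one.  Pointwise
#' confidence intervals come from the delta method on the linear predictor
#' (normal quantiles on eta, exponentiated, scaled by the same constant);
#' by default the scaling constant is the maximum point prediction, with
#' `scale = "max_upper"` scaling by the maximum of the upper confidence
#' bound instead.
#'
#' @param fit a `dcgam` fit.
#' @param covariate covariate name (e.g. "UOCW").
#' @param data data supplying the percentile grid and rug (defaults to the
#'   fitting data).
#' @param n_grid grid size (default 100).
#' @param level confidence level (default 0.90).
#' @param scale `"max_fit"` (default) or `"max_upper"`.
#' @return data.frame of class `response_function` with columns `grid`,
#'   `ratio`, `ci_low`, `ci_high`; rug values (used / available covariate
#'   values) are kept in attributes for plotting.
#' @export
response_function <- function(fit, covariate, data = fit$data,
                              n_grid = 100, level = 0.90,
                              scale = c("max_fit", "max_upper")) {
  stopifnot(inherits(fit, "dcgam"))
  scale <- match.arg(scale)
  cols <- covariate_columns()
  if (!covariate %in% names(cols)) stop("unknown covariate ", covariate)
  x_all <- data[[cols[covariate]]]
  if (is.null(x_all)) stop("covariate column missing from data")
  x_use <- x_all[data$used == 1]
  qs <- stats::quantile(x_use, c(0.1, 0.9), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = n_grid)

  if (!length(fit$terms)) {
    # null model: selection is flat and exact, no sampling uncertainty
    out <- data.frame(grid = grid, ratio = 1, ci_low = 1, ci_high = 1)
  } else {
    if (!covariate %in% names(fit$terms)) {
      stop("covariate ", covariate, " is not a term of model '",
           fit$model$name, "'")
    }
    t_ <- fit$terms[[covariate]]
    Xg <- if (t_$type == "smooth") spline_eval(t_$basis, grid)
          else matrix(grid - t_$center, ncol = 1)
    blk <- fit$blocks[[covariate]]
    eta <- drop(Xg %*% fit$coefficients[blk])
    # the ratio is peak-referenced, so its uncertainty is that of the
    # contrast eta(g) - eta(peak): the delta-method variance of the
    # difference, zero at the peak itself
    pk <- which.max(eta)
    Xc <- sweep(Xg, 2, Xg[pk, ])
    se <- sqrt(pmax(0, rowSums((Xc %*% fit$vcov[blk, blk, drop = FALSE]) *
                                 Xc)))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ref <- if (scale == "max_fit") max(eta) else max(eta + z * se)
    out <- data.frame(grid = grid,
                      ratio = exp(eta - ref),
                      ci_low = exp(eta - z * se - ref),
                      ci_high = exp(eta + z * se - ref))
  }
  attr(out, "covariate") <- covariate
  attr(out, "scale") <- scale
  attr(out, "level") <- level
  attr(out, "rug_used") <- x_use
  attr(out, "rug_available") <- x_all[data$used == 0]
  class(out) <- c("response_function", "data.frame")
  out
}

#' Peak and plateau onset of a response function
#'
#' The peak is the grid value maximizing the relative selection ratio; the
#' plateau onset is the smallest grid value whose upper confidence bound
#' reaches the peak's lower bound, i.e. the first covariate value whose
#' selection ratio is statistically similar (overlapping confidence
#' intervals) to the maximum.
#'
#' @param rf a [response_function()].
#' @return named numeric vector `c(peak_value, plateau_low)`.
#' @export
peak_and_plateau <- function(rf) {
  stopifnot(inherits(rf, "response_function"))
  pk <- which.max(rf$ratio)
  similar <- rf$ci_high >= rf$ci_low[pk]
  c(peak_value = rf$grid[pk],
    plateau_low = rf$grid[which(similar)[1]])
}
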