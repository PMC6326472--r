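#' Rank candidate models by AIC with Akaike weights
#'
#' Computes `delta_aic = aic - min(aic)` and Akaike weights
#' `exp(-delta/2) / sum(exp(-delta/2))`, and applies the parsimony rule:
#' among models with `delta_aic <= delta_max` (default 2.0), the selected
#' model is the one with the fewest covariates, ties broken by the lower
#' AIC.
#'
#' @param fits either a list of `dcgam` fits on the same data, or a
#'   data.frame with columns `model`, `aic`, `n_cov` (and optionally `df`)
#'   for ranking externally supplied AIC values.
#' @param delta_max parsimony window on delta AIC (default 2).
#' @return a data.frame of class `model_ranking`, ordered by AIC, with
#'   columns `model`, `n_cov`, `df`, `aic`, `delta_aic`, `weight`,
#'   `selected`; the selected model's name is in
#'   `attr(, "selected_model")`.
#' @export
rank_models <- function(fits, delta_max = 2) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("model", "aic", "n_cov") %in% names(fits)))
    tab <- data.frame(model = as.character(fits$model),
                      n_cov = fits$n_cov,
                      df = if ("df" %in% names(fits)) fits$df else NA_real_,
                      aic = fits$aic)
  } else {
    stopifnot(length(fits) >= 1,
              all(vapply(fits, inherits, logical(1), "dcgam")))
    n_sets <- vapply(fits, function(f) f$n_sets, numeric(1))
    if (length(unique(n_sets)) != 1) {
      stop("fits were made on differing numbers of choice sets")
    }
    tab <- data.frame(
      model = vapply(fits, function(f) f$model$name, ""),
      n_cov = vapply(fits, function(f) length(f$model$covariates), 0L),
      df = vapply(fits, function(f) f$edf_total, numeric(1)),
      aic = vapply(fits, function(f) f$aic, numeric(1)))
  }
  tab$delta_aic <- tab$aic - min(tab$aic)
  w <- exp(-tab$delta_aic / 2)
  tab$weight <- w / sum(w)
  in_window <- which(tab$delta_aic <= delta_max)
  sel <- in_window[order(tab$n_cov[in_window], tab$aic[in_window])][1]
  tab$selected <- seq_len(nrow(tab)) == sel
  tab <- tab[order(tab$aic), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "selected_model") <- tab$model[tab$selected]
  class(tab) <- c("model_ranking", "data.frame")
  tab
}
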