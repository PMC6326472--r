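#' Specification of the generating (true) selection surface
#'
#' The generating truth is a plateau-shaped log selection weight in
#' unobstructed channel width and nearest-forest distance,
#' `beta * min(x, plateau) / plateau`: selection rises linearly with the
#' covariate until the plateau onset and is flat beyond it, mirroring the
#' saturating response shapes this analysis is designed to recover.  The
#' remaining covariates (TCW, UFCW, UD, DIS) carry no effect by
#' construction: they are nuisance metrics, partially correlated with the
#' drivers only through the shared channel geometry.
#'
#' @param uocw_plateau,uocw_beta plateau onset (m) and log-weight gain of
#'   the unobstructed-channel-width effect.
#' @param nf_plateau,nf_beta same for the nearest-forest effect.
#' @param n_use number of stopover events to simulate.
#' @param n_avail available alternatives per choice set (default 20, so a
#'   choice set holds 21 alternatives).
#' @param window_m half-width of the availability window along the river
#'   (default 16 km up- and downstream).
#' @return list of class `selection_spec`.
#' @export
selection_spec <- function(uocw_plateau = 200, uocw_beta = 3,
                           nf_plateau = 160, nf_beta = 2,
                           n_use = 85, n_avail = 20, window_m = 16000) {
  stopifnot(uocw_plateau > 0, is.finite(uocw_plateau),
            nf_plateau > 0, is.finite(nf_plateau),
            n_use >= 1, n_avail >= 1, window_m > 0)
  structure(as.list(environment()), class = "selection_spec")
}

#' True log selection weight under a generating specification
#'
#' @param spec a [selection_spec()].
#' @param uocw,nf covariate values (m).
#' @return numeric log-weights (the exponent of the multinomial weight).
#' @export
true_log_weight <- function(spec, uocw, nf) {
  spec$uocw_beta * pmin(uocw, spec$uocw_plateau) / spec$uocw_plateau +
    spec$nf_beta * pmin(nf, spec$nf_plateau) / spec$nf_plateau
}

#' Simulate stopover choice sets from a landscape and a known truth
#'
#' For each stopover, a window anchor is drawn so the full +/- window fits
#' inside the landscape, `n_avail + 1` candidate points are sampled
#' uniformly by area within the roostable wetted channel of that window,
#' and one of them is marked as used with probability proportional to
#' `exp(true_log_weight)` -- the multinomial-logit form the downstream
#' model assumes.  Each stopover draws a survey date (and with it the mean
#' daily discharge driving the flow covariates) from the landscape's date
#' table.
#'
#' @param land a `river_landscape`.
#' @param spec a [selection_spec()].
#' @param seed integer seed; output is deterministic given (land, spec,
#'   seed).
#' @return a `choice_data` data.frame (see [write_choice_csv()] for the
#'   column contract).
#' @export
simulate_stopovers <- function(land, spec, seed = 1L) {
  stopifnot(inherits(land, "river_landscape"),
            inherits(spec, "selection_spec"))
  W <- spec$window_m
  if (land$extent_m < 2 * W) {
    stop("landscape shorter than one availability window (2 x ", W, " m)")
  }
  n_alt <- spec$n_avail + 1L
  rows <- vector("list", spec$n_use)
  anchors <- with_seed(derive_seed(seed, "anchors"), {
    a <- stats::runif(spec$n_use, 0, land$extent_m)
    for (try in 1:100) {
      bad <- a < W | a > land$extent_m - W  # window would leave landscape
      if (!any(bad)) break
      a[bad] <- stats::runif(sum(bad), 0, land$extent_m)
    }
    if (any(a < W | a > land$extent_m - W)) {
      stop("could not place availability windows inside the landscape ",
           "after 100 resampling attempts")
    }
    a
  })
  date_idx <- with_seed(derive_seed(seed, "dates"),
                        sample.int(nrow(land$dates), spec$n_use,
                                   replace = TRUE))
  for (i in seq_len(spec$n_use)) {
    rows[[i]] <- sample_inchannel(land, anchors[i] - W, anchors[i] + W,
                                  n_alt, derive_seed(seed, "points", i))
  }
  pts <- do.call(rbind, rows)
  drows <- land$dates[date_idx, ]
  met <- attach_metrics(land, pts[, "s"], pts[, "t"],
                        rep(drows$discharge_cms, each = n_alt))
  lw <- true_log_weight(spec, met$uocw_m, met$nf_m)
  used <- integer(nrow(pts))
  for (i in seq_len(spec$n_use)) {
    rr <- (i - 1L) * n_alt + seq_len(n_alt)
    pr <- exp(lw[rr] - max(lw[rr]))
    used_idx <- with_seed(derive_seed(seed, "choice", i),
                          sample.int(n_alt, 1, prob = pr))
    used[rr[used_idx]] <- 1L
  }
  out <- data.frame(
    set_id = rep(seq_len(spec$n_use), each = n_alt),
    alt_id = rep(seq_len(n_alt), spec$n_use),
    used = used,
    x_m = pts[, "s"],
    met,
    season = rep(drows$season, each = n_alt),
    date = rep(as.character(drows$date), each = n_alt),
    row.names = NULL)
  attr(out, "window_m") <- W
  attr(out, "anchors") <- anchors
  class(out) <- c("choice_data", "data.frame")
  out
}
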