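#' Configuration for the synthetic river landscape generator
#'
#' Parameters describe a braided sand-bed river corridor: a gently sinuous
#' centerline, a lognormal smoothly-varying total channel width whose
#' unobstructed-width field spans roughly 50-450 m between the 10th and 90th
#' percentiles, densely vegetated in-channel islands that segment the
#' channel, riparian forest patches along (and occasionally encroaching
#' over) the banks, and a table of survey dates with mean daily discharge.
#'
#' @param extent_km corridor length in river km (>= 32 so one full +/-16 km
#'   availability window fits).
#' @param width_mid geometric median total channel width (m).
#' @param width_sigma lognormal sd of the width field on the log scale.
#' @param width_corr_len correlation length of the width field (m).
#' @param width_range hard clamp on total channel width (m).
#' @param uocw_range target 10th/90th percentile range of unobstructed
#'   channel width (m), used only for post-generation checks.
#' @param wetted_frac fraction of total channel width that is wetted under
#'   reference flow; defines the band available for roosting points and the
#'   region dense vegetation islands may occupy.
#' @param sinuosity_amp,sinuosity_wavelength centerline sine amplitude and
#'   wavelength (m); curvature is kept far below 1/width so perpendicular
#'   transects do not cross.
#' @param veg_per_km expected dense-vegetation islands per river km.
#' @param veg_len_range island length range along the channel (m).
#' @param veg_wfrac_range island width as a fraction of the local wetted
#'   width.
#' @param forest_per_km expected riparian forest patches per km per bank.
#' @param forest_len_range patch length range (m).
#' @param forest_depth_range patch depth away from the river (m).
#' @param forest_setback_max maximum setback of a patch behind the bank (m).
#' @param forest_encroach_prob probability a patch encroaches over the bank
#'   into the dry channel margin (between wetted edge and bank), which is
#'   what makes unforested channel width fall below total channel width.
#' @param n_dates number of survey dates to simulate.
#' @param discharge_meanlog,discharge_sdlog lognormal parameters of mean
#'   daily discharge (cms).
#' @return a list of class `landscape_config`.
#' @export
landscape_config <- function(extent_km = 145,
                             width_mid = 95,
                             width_sigma = 0.9,
                             width_corr_len = 1500,
                             width_range = c(30, 900),
                             uocw_range = c(50, 450),
                             wetted_frac = 0.7,
                             sinuosity_amp = 200,
                             sinuosity_wavelength = 20000,
                             veg_per_km = 0.6,
                             veg_len_range = c(150, 700),
                             veg_wfrac_range = c(0.12, 0.45),
                             forest_per_km = 0.45,
                             forest_len_range = c(400, 2500),
                             forest_depth_range = c(100, 400),
                             forest_setback_max = 330,
                             forest_encroach_prob = 0.3,
                             n_dates = 200,
                             discharge_meanlog = log(40),
                             discharge_sdlog = 0.45) {
  cfg <- as.list(environment())
  class(cfg) <- "landscape_config"
  cfg
}

#' Generate a seeded synthetic river landscape
#'
#' The channel is represented exactly as a width profile around a smooth
#' centerline: every geometric query (transect widths, point sampling) is
#' answered in curvilinear (arc-length s, offset t) coordinates, and planar
#' coordinates are produced by offsetting along the centerline normal.
#' Vegetation islands and forest patches are axis-aligned rectangles in
#' (s, t); their planar images are gently curved quadrilaterals.
#'
#' @param config a [landscape_config()].
#' @param seed integer seed; the same seed always yields a byte-identical
#'   landscape (and GeoJSON serialization).
#' @return an object of class `river_landscape`.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L) {
  if (config$extent_km < 32) {
    stop("extent_km must be >= 32 km so that one full 32 km availability ",
         "window (16 km up- and downstream) fits inside the landscape")
  }
  stopifnot(config$width_mid > 0, config$width_sigma >= 0,
            config$wetted_frac > 0, config$wetted_frac <= 1)
  L <- config$extent_km * 1000

  land <- with_seed(derive_seed(seed, "landscape"), {
    # stationary Gaussian field for log-width via random spectral synthesis;
    # marginal is N(0, 1) for any K, correlation length ~ width_corr_len
    K <- 64L
    omega <- stats::rnorm(K, 0, 1 / config$width_corr_len)
    phase <- stats::runif(K, 0, 2 * pi)

    grid_s <- seq(0, L, by = 25)
    wfun <- function(s) {
      z <- sqrt(2 / K) *
        rowSums(cos(outer(s, omega) + rep(phase, each = length(s))))
      pmin(pmax(config$width_mid * exp(config$width_sigma * z),
                config$width_range[1]), config$width_range[2])
    }
    w_grid <- wfun(grid_s)

    # dense-vegetation islands inside the wetted band
    n_veg <- stats::rpois(1, config$veg_per_km * config$extent_km)
    veg <- data.frame(s0 = numeric(0), s1 = numeric(0),
                      t0 = numeric(0), t1 = numeric(0))
    if (n_veg > 0) {
      s0 <- sort(stats::runif(n_veg, 0, L))
      len <- stats::runif(n_veg, config$veg_len_range[1],
                          config$veg_len_range[2])
      s1 <- pmin(s0 + len, L)
      frac <- stats::runif(n_veg, config$veg_wfrac_range[1],
                           config$veg_wfrac_range[2])
      t0 <- t1 <- numeric(n_veg)
      for (i in seq_len(n_veg)) {
        idx <- grid_s >= s0[i] & grid_s <= s1[i]
        hw <- config$wetted_frac * min(w_grid[idx]) / 2  # narrowest point
        halfw <- frac[i] * hw
        ctr <- stats::runif(1, -(hw - halfw), hw - halfw)
        t0[i] <- ctr - halfw
        t1[i] <- ctr + halfw
      }
      veg <- data.frame(s0 = s0, s1 = s1, t0 = t0, t1 = t1)
    }

    # riparian forest patches, one Poisson process per bank; side = +1/-1
    forest <- data.frame(s0 = numeric(0), s1 = numeric(0),
                         t0 = numeric(0), t1 = numeric(0))
    for (side in c(1, -1)) {
      n_f <- stats::rpois(1, config$forest_per_km * config$extent_km)
      if (n_f == 0) next
      s0 <- sort(stats::runif(n_f, 0, L))
      len <- stats::runif(n_f, config$forest_len_range[1],
                          config$forest_len_range[2])
      s1 <- pmin(s0 + len, L)
      depth <- stats::runif(n_f, config$forest_depth_range[1],
                            config$forest_depth_range[2])
      encroach <- stats::runif(n_f) < config$forest_encroach_prob
      setback <- stats::runif(n_f, 0, config$forest_setback_max)
      u <- stats::runif(n_f)
      t_in <- numeric(n_f)
      for (i in seq_len(n_f)) {
        idx <- grid_s >= s0[i] & grid_s <= s1[i]
        bank_max <- max(w_grid[idx]) / 2
        wet_max <- config$wetted_frac * max(w_grid[idx]) / 2
        if (encroach[i]) {
          # inner edge inside the dry margin, never inside the wetted band
          t_in[i] <- wet_max + u[i] * (bank_max - wet_max)
        } else {
          t_in[i] <- bank_max + setback[i]
        }
      }
      forest <- rbind(forest,
                      data.frame(s0 = s0, s1 = s1,
                                 t0 = side * t_in,
                                 t1 = side * (t_in + depth)))
    }
    # normalize so t0 < t1 on either bank
    if (nrow(forest)) {
      swap <- forest$t0 > forest$t1
      tmp <- forest$t0[swap]
      forest$t0[swap] <- forest$t1[swap]
      forest$t1[swap] <- tmp
      forest <- forest[order(forest$s0), , drop = FALSE]
      rownames(forest) <- NULL
    }

    # survey dates: spring (Mar 21 - Apr 29) and fall (Oct 9 - Nov 10)
    nd <- config$n_dates
    year <- sample(2001:2017, nd, replace = TRUE)
    season <- sample(c("spring", "fall"), nd, replace = TRUE)
    doy <- ifelse(season == "spring",
                  sample(80:119, nd, replace = TRUE),
                  sample(282:314, nd, replace = TRUE))
    date <- as.Date(doy - 1, origin = paste0(year, "-01-01"))
    discharge <- stats::rlnorm(nd, config$discharge_meanlog,
                               config$discharge_sdlog)
    ord <- order(date)
    dates <- data.frame(date = date[ord], season = season[ord],
                        discharge_cms = round(discharge[ord], 3))
    rownames(dates) <- NULL

    structure(
      list(extent_m = L,
           spectral = list(K = K, omega = omega, phase = phase),
           veg = veg, forest = forest, dates = dates,
           config = config, seed = as.integer(seed)),
      class = "river_landscape")
  })
  land
}

#' @export
print.river_landscape <- function(x, ...) {
  cat("<river_landscape> ", x$extent_m / 1000, " km, ",
      nrow(x$veg), " vegetation islands, ", nrow(x$forest),
      " forest patches, ", nrow(x$dates), " survey dates (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

# total channel width (m) at arc-length s -- vectorized
tcw_profile <- function(land, s) {
  cfg <- land$config
  sp <- land$spectral
  z <- sqrt(2 / sp$K) *
    rowSums(cos(outer(s, sp$omega) + rep(sp$phase, each = length(s))))
  pmin(pmax(cfg$width_mid * exp(cfg$width_sigma * z), cfg$width_range[1]),
       cfg$width_range[2])
}

wetted_halfwidth <- function(land, s) {
  land$config$wetted_frac * tcw_profile(land, s) / 2
}

# centerline point and unit normal at arc-length s.  The sine amplitude is
# small relative to its wavelength, so arc length along the curve is within
# a fraction of a percent of the x ordinate; we parameterize by x = s and
# accept that tiny stretch (documented, sub-metre over any transect).
centerline_xy <- function(land, s) {
  A <- land$config$sinuosity_amp
  lam <- land$config$sinuosity_wavelength
  cbind(x = s, y = A * sin(2 * pi * s / lam))
}

centerline_normal <- function(land, s) {
  A <- land$config$sinuosity_amp
  lam <- land$config$sinuosity_wavelength
  dy <- A * (2 * pi / lam) * cos(2 * pi * s / lam)
  nrm <- sqrt(1 + dy^2)
  cbind(nx = -dy / nrm, ny = 1 / nrm)
}

#' Convert curvilinear river coordinates to planar coordinates
#'
#' @param land a `river_landscape`.
#' @param s arc-length along the centerline (m).
#' @param t signed perpendicular offset from the centerline (m, left bank
#'   positive).
#' @return a two-column matrix of planar x/y (m).
#' @export
river_to_planar <- function(land, s, t) {
  p <- centerline_xy(land, s)
  n <- centerline_normal(land, s)
  cbind(x = p[, 1] + t * n[, 1], y = p[, 2] + t * n[, 2])
}

#' Project planar points onto the river centerline
#'
#' Returns the curvilinear (s, t) coordinates of each point: s is the
#' arc-length of the nearest centerline point, t the signed perpendicular
#' offset.  Inversion is well defined because centerline curvature radius
#' far exceeds any channel half-width.
#'
#' @param land a `river_landscape`.
#' @param x,y planar coordinates (m).
#' @return a two-column matrix of (s, t).
#' @export
planar_to_river <- function(land, x, y) {
  n <- length(x)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("s", "t")))
  for (i in seq_len(n)) {
    f <- function(s) {
      p <- centerline_xy(land, s)
      (p[1] - x[i])^2 + (p[2] - y[i])^2
    }
    lo <- max(0, x[i] - 2000)
    hi <- min(land$extent_m, x[i] + 2000)
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-6)
    s <- opt$minimum
    nv <- centerline_normal(land, s)
    p <- centerline_xy(land, s)
    out[i, ] <- c(s, (x[i] - p[1]) * nv[1] + (y[i] - p[2]) * nv[2])
  }
  out
}

# Uniform-by-area sampling of roostable in-channel points: inside the
# wetted band, outside dense-vegetation islands, s in [s_lo, s_hi].
# Plain 2D rejection against the wetted half-width envelope.
sample_inchannel <- function(land, s_lo, s_hi, n, seed) {
  with_seed(seed, {
    hw_cap <- land$config$wetted_frac * land$config$width_range[2] / 2
    veg <- land$veg[land$veg$s1 >= s_lo & land$veg$s0 <= s_hi, ,
                    drop = FALSE]
    out_s <- numeric(0)
    out_t <- numeric(0)
    guard <- 0L
    while (length(out_s) < n) {
      guard <- guard + 1L
      if (guard > 1000L) {
        stop("failed to sample in-channel points in window [", s_lo, ", ",
             s_hi, "] after 1000 batches")
      }
      m <- max(8L * (n - length(out_s)), 256L)
      s <- stats::runif(m, s_lo, s_hi)
      t <- stats::runif(m, -hw_cap, hw_cap)
      ok <- abs(t) < wetted_halfwidth(land, s)
      for (k in seq_len(nrow(veg))) {
        ok <- ok & !(s >= veg$s0[k] & s <= veg$s1[k] &
                       t >= veg$t0[k] & t <= veg$t1[k])
      }
      out_s <- c(out_s, s[ok])
      out_t <- c(out_t, t[ok])
    }
    cbind(s = out_s[seq_len(n)], t = out_t[seq_len(n)])
  })
}
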