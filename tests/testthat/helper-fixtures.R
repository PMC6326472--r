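# Hand-built landscapes with exactly known geometry, and independent
# brute-force oracles used to cross-check the analytic metric code.

# constant-width channel: spectral field is identically zero and the
# width clamp pins the profile at `width`
make_test_landscape <- function(width = 200, extent_km = 40,
                                veg = NULL, forest = NULL,
                                wetted_frac = 0.7,
                                sinuosity_amp = 200,
                                discharge = 40) {
  cfg <- landscape_config(extent_km = extent_km,
                          width_mid = width, width_sigma = 0,
                          width_range = c(width, width),
                          wetted_frac = wetted_frac,
                          sinuosity_amp = sinuosity_amp,
                          n_dates = 1)
  empty <- data.frame(s0 = numeric(0), s1 = numeric(0),
                      t0 = numeric(0), t1 = numeric(0))
  structure(
    list(extent_m = extent_km * 1000,
         spectral = list(K = 1L, omega = 0, phase = pi / 2),
         veg = if (is.null(veg)) empty else veg,
         forest = if (is.null(forest)) empty else forest,
         dates = data.frame(date = as.Date("2010-04-01"),
                            season = "spring",
                            discharge_cms = discharge),
         config = cfg, seed = 0L),
    class = "river_landscape")
}

# small, fast default landscape for simulation-based tests
small_landscape <- function(seed = 1, extent_km = 40) {
  generate_landscape(landscape_config(extent_km = extent_km), seed)
}

# raster-counting width oracle: sample the transect at `step` metres,
# classify every cell against the patch tables, and count the contiguous
# free run containing the point
oracle_widths <- function(land, s, t, step = 0.1) {
  s <- unname(s)
  t <- unname(t)
  w <- unname(riversel:::tcw_profile(land, s))
  u <- seq(-w / 2 + step / 2, w / 2 - step / 2, by = step)
  in_patch <- function(patches) {
    hit <- rep(FALSE, length(u))
    for (k in seq_len(nrow(patches))) {
      if (patches$s0[k] <= s && s <= patches$s1[k]) {
        hit <- hit | (u >= patches$t0[k] & u <= patches$t1[k])
      }
    }
    hit
  }
  veg_hit <- in_patch(land$veg)
  for_hit <- in_patch(land$forest)
  run_len <- function(blocked) {
    free <- !blocked
    id <- cumsum(c(TRUE, diff(free) != 0))
    sel <- which.min(abs(u - t))
    sum(id == id[sel] & free) * step
  }
  c(uocw = run_len(veg_hit | for_hit), tcw = w, ufcw = run_len(for_hit))
}

# boundary-sampling nearest-forest oracle: densify every patch boundary
# in planar space and take the minimum point-to-vertex distance
oracle_nf <- function(land, s, t, cap = 400, step = 0.2) {
  fp <- land$forest
  if (!nrow(fp)) return(cap)
  p <- river_to_planar(land, s, t)
  best <- Inf
  for (k in seq_len(nrow(fp))) {
    ds <- max(0, fp$s0[k] - s, s - fp$s1[k])
    if (ds > cap + 50) next
    ss <- seq(fp$s0[k], fp$s1[k],
              by = min(step, fp$s1[k] - fp$s0[k]))
    tt <- seq(fp$t0[k], fp$t1[k],
              by = min(step, fp$t1[k] - fp$t0[k]))
    vs <- rbind(river_to_planar(land, ss, rep(fp$t0[k], length(ss))),
                river_to_planar(land, ss, rep(fp$t1[k], length(ss))),
                river_to_planar(land, rep(fp$s0[k], length(tt)), tt),
                river_to_planar(land, rep(fp$s1[k], length(tt)), tt))
    best <- min(best, sqrt((vs[, 1] - p[1])^2 + (vs[, 2] - p[2])^2))
  }
  min(best, cap)
}

# brute-force conditional-logit log-likelihood (naive, no log-sum-exp)
oracle_loglik <- function(eta, set_id, used) {
  s <- 0
  for (id in unique(set_id)) {
    rows <- set_id == id
    w <- exp(eta[rows])
    s <- s + log(w[used[rows] == 1] / sum(w))
  }
  s
}

# tiny random choice-data tables for likelihood tests (no geometry)
random_choice_data <- function(n_sets, n_alt, seed) {
  withr::with_seed(seed, {
    n <- n_sets * n_alt
    data.frame(set_id = rep(seq_len(n_sets), each = n_alt),
               alt_id = rep(seq_len(n_alt), n_sets),
               used = as.vector(replicate(n_sets, {
                 u <- integer(n_alt)
                 u[sample.int(n_alt, 1)] <- 1L
                 u
               })),
               x_m = runif(n, 0, 1000),
               uocw_m = runif(n, 20, 500),
               nf_m = runif(n, 0, 400),
               tcw_m = runif(n, 50, 700),
               ufcw_m = runif(n, 30, 600),
               ud_cms_per_m = runif(n, 0.01, 1),
               dis_cms_per_m = runif(n, 0.01, 0.5),
               season = "spring", date = "2010-04-01")
  })
}
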