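#' Transect-based channel width metrics at an in-channel point
#'
#' The transect is the straight planar line through the point running
#' perpendicular to the centerline tangent at the point's arc-length
#' projection.  Total channel width (TCW) is the bank-to-bank intersection
#' length; unobstructed channel width (UOCW) is the length of the free
#' transect segment containing the point after removing every obstruction
#' (dense vegetation islands and any forest encroaching over the bank), so
#' that when a densely vegetated island segments the channel, only the
#' portion containing the point counts; unforested channel width (UFCW)
#' removes forest intersections only.  Hence UOCW <= UFCW <= TCW.
#'
#' @param land a `river_landscape`.
#' @param s,t curvilinear point coordinates (vectors, m); see
#'   [planar_to_river()] for planar input.
#' @return a data.frame with columns `uocw`, `tcw`, `ufcw` (m).
#' @export
measure_widths <- function(land, s, t) {
  stopifnot(length(s) == length(t))
  w <- tcw_profile(land, s)
  bad <- abs(t) >= w / 2
  if (any(bad)) {
    stop("point(s) outside the channel polygon at s = ",
         paste(signif(s[bad][1], 6)), " m")
  }
  n <- length(s)
  hw <- w / 2
  # free-segment bounds around each point, updated patch-by-patch:
  # an obstruction interval ending below the point raises the lower bound
  # of the point's containing segment; one starting above lowers the
  # upper bound.  Applied to vegetation+forest for UOCW, forest for UFCW.
  lo_o <- lo_f <- -hw
  hi_o <- hi_f <- hw
  update_bounds <- function(patches, forest_only) {
    for (k in seq_len(nrow(patches))) {
      idx <- which(s >= patches$s0[k] & s <= patches$s1[k])
      if (!length(idx)) next
      t0 <- pmax(patches$t0[k], -hw[idx])
      t1 <- pmin(patches$t1[k], hw[idx])
      real <- t1 > t0
      inside <- real & t0 <= t[idx] & t[idx] <= t1
      if (any(inside)) {
        stop("point at s = ", signif(s[idx][inside][1], 6), " m lies ",
             if (forest_only) "inside forest"
             else "on a densely vegetated island")
      }
      below <- real & t1 <= t[idx]
      above <- real & t0 >= t[idx]
      if (forest_only) {
        lo_f[idx] <<- ifelse(below, pmax(lo_f[idx], t1), lo_f[idx])
        hi_f[idx] <<- ifelse(above, pmin(hi_f[idx], t0), hi_f[idx])
      }
      lo_o[idx] <<- ifelse(below, pmax(lo_o[idx], t1), lo_o[idx])
      hi_o[idx] <<- ifelse(above, pmin(hi_o[idx], t0), hi_o[idx])
    }
  }
  update_bounds(land$veg, forest_only = FALSE)
  update_bounds(land$forest, forest_only = TRUE)
  data.frame(uocw = hi_o - lo_o, tcw = w, ufcw = hi_f - lo_f)
}

#' Distance to the nearest riparian forest patch, truncated at 400 m
#'
#' Planar Euclidean point-to-polygon distance, measured in any direction
#' from the point itself (not along the transect, and not from the channel
#' edge), then truncated: distances beyond `cap` are recorded as `cap`
#' because forest that far away is taken to have no influence on roost
#' choice.  Because forest patches are normal-offset rectangles around the
#' same centerline as the point, the inner patch edge is a parallel curve
#' and the exact planar distance reduces to offset arithmetic when the
#' point's arc-length lies within the patch extent, and to a point-segment
#' distance against the patch's straight end edge otherwise.
#'
#' @param land a `river_landscape`.
#' @param s,t curvilinear point coordinates (m).
#' @param cap truncation distance (m), default 400.
#' @return numeric vector of distances in `[0, cap]`.
#' @export
measure_nf <- function(land, s, t, cap = 400) {
  stopifnot(length(s) == length(t))
  n <- length(s)
  out <- rep(cap, n)
  fp <- land$forest
  if (!nrow(fp)) return(out)
  p_xy <- river_to_planar(land, s, t)
  for (k in seq_len(nrow(fp))) {
    s0 <- fp$s0[k]; s1 <- fp$s1[k]; t0 <- fp$t0[k]; t1 <- fp$t1[k]
    ds <- pmax(0, pmax(s0 - s, s - s1))
    dt <- pmax(0, pmax(t0 - t, t - t1))
    cand <- which(sqrt(ds^2 + dt^2) < out + 25)  # curvilinear prefilter
    if (!length(cand)) next
    inside_s <- s[cand] >= s0 & s[cand] <= s1
    d <- numeric(length(cand))
    # arc-length within patch extent: parallel-curve offset distance
    d[inside_s] <- pmax(t0 - t[cand][inside_s], t[cand][inside_s] - t1, 0)
    # otherwise: planar distance to the straight end edge (incl. corners)
    if (any(!inside_s)) {
      io <- which(!inside_s)
      for (j in io) {
        se <- if (s[cand][j] < s0) s0 else s1
        ab <- river_to_planar(land, c(se, se), c(t0, t1))
        d[j] <- point_segment_distance(p_xy[cand[j], 1], p_xy[cand[j], 2],
                                       ab[1, 1], ab[1, 2], ab[2, 1], ab[2, 2])
      }
    }
    out[cand] <- pmin(out[cand], d)
  }
  pmin(out, cap)
}

point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  u <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((ax + u * vx - px)^2 + (ay + u * vy - py)^2)
}

#' Flow metrics: unit discharge and discharge per total channel width
#'
#' @param discharge mean daily discharge (cms).
#' @param wetted_width wetted width of the active channel at the point (m).
#' @param tcw total channel width (m).
#' @return data.frame with `ud` (cms per m wetted width) and `dis` (cms per
#'   m total channel width); `ud >= dis` whenever wetted width <= TCW.
#' @export
flow_metrics <- function(discharge, wetted_width, tcw) {
  if (any(wetted_width <= 0) || any(tcw <= 0)) {
    stop("channel widths must be positive to compute flow metrics")
  }
  if (any(discharge < 0)) stop("discharge must be non-negative")
  data.frame(ud = discharge / wetted_width, dis = discharge / tcw)
}

# wetted width fraction of TCW on a given date; grows sublinearly with
# discharge around the reference flow, clamped inside the channel
wetted_frac_for_discharge <- function(cfg, discharge) {
  pmin(0.95, pmax(0.3, cfg$wetted_frac *
                          (discharge / exp(cfg$discharge_meanlog))^0.25))
}

#' Attach all six habitat covariates to in-channel points
#'
#' Batch convenience used by the simulator and the choice-set builder:
#' computes UOCW/TCW/UFCW (transect widths), NF (truncated nearest-forest
#' distance) and the flow metrics UD/DIS for a per-point discharge.
#'
#' @param land a `river_landscape`.
#' @param s,t point coordinates (m).
#' @param discharge per-point mean daily discharge (cms), recycled.
#' @return data.frame with columns `uocw_m`, `tcw_m`, `ufcw_m`, `nf_m`,
#'   `ud_cms_per_m`, `dis_cms_per_m`.
#' @export
attach_metrics <- function(land, s, t, discharge) {
  wid <- measure_widths(land, s, t)
  nf <- measure_nf(land, s, t)
  discharge <- rep_len(discharge, length(s))
  wf <- wetted_frac_for_discharge(land$config, discharge)
  fl <- flow_metrics(discharge, wf * wid$tcw, wid$tcw)
  data.frame(uocw_m = wid$uocw, tcw_m = wid$tcw, ufcw_m = wid$ufcw,
             nf_m = nf, ud_cms_per_m = fl$ud, dis_cms_per_m = fl$dis)
}
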