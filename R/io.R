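choice_csv_columns <- function() {
  c("set_id", "alt_id", "used", "x_m", "uocw_m", "nf_m", "tcw_m",
    "ufcw_m", "ud_cms_per_m", "dis_cms_per_m", "season", "date")
}

#' Write choice-set data to CSV
#'
#' Shared tabular dialect of the pipeline: one row per alternative,
#' columns `set_id, alt_id, used, x_m, uocw_m, nf_m, tcw_m, ufcw_m,
#' ud_cms_per_m, dis_cms_per_m, season, date`; numerics carry 6
#' significant digits, so a write/read/write cycle is byte-stable.
#'
#' @param data a `choice_data` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_choice_csv <- function(data, path) {
  cols <- choice_csv_columns()
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("choice data is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_choice_rows(data)
  out <- data[, cols]
  for (nm in c("x_m", "uocw_m", "nf_m", "tcw_m", "ufcw_m",
               "ud_cms_per_m", "dis_cms_per_m")) {
    out[[nm]] <- as.character(signif(out[[nm]], 6))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read choice-set data from CSV
#'
#' Validates the dialect on read: all columns present, no duplicate
#' (set_id, alt_id), and exactly one used alternative per set; violations
#' raise an error naming the offending set or row.
#'
#' @param path CSV file path.
#' @return a `choice_data` data.frame.
#' @export
read_choice_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(choice_csv_columns(), names(df))
  if (length(missing_cols)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, choice_csv_columns()]
  validate_choice_rows(df)
  class(df) <- c("choice_data", "data.frame")
  df
}

validate_choice_rows <- function(df) {
  key <- paste(df$set_id, df$alt_id)
  if (anyDuplicated(key)) {
    stop("duplicate (set_id, alt_id) at row ",
         which(duplicated(key))[1])
  }
  n_used <- tapply(df$used, df$set_id, sum)
  bad <- names(n_used)[n_used != 1]
  if (length(bad)) {
    stop("choice set ", bad[1], " has ", n_used[bad[1]],
         " used rows (expected exactly 1)")
  }
  invisible(TRUE)
}

# --- landscape GeoJSON -------------------------------------------------

#' Serialize a landscape to GeoJSON
#'
#' Writes a FeatureCollection in a local planar metre CRS with features
#' tagged `role = centerline | channel | dense_veg | forest`.  The
#' generator's parametric description (width field spectrum, patch tables,
#' date table, seed) is embedded under the top-level `riversel` key so the
#' landscape round-trips losslessly; the polygon features are densified
#' planar images for display and interchange.
#'
#' @param land a `river_landscape`.
#' @param path output path.
#' @param ds densification step along the channel (m).
#' @return `path`, invisibly.
#' @export
write_landscape_geojson <- function(land, path, ds = 50) {
  s_grid <- seq(0, land$extent_m, by = ds)
  if (s_grid[length(s_grid)] < land$extent_m) {
    s_grid <- c(s_grid, land$extent_m)
  }
  ring <- function(s0, s1, t0fun, t1fun, step) {
    ss <- seq(s0, s1, length.out = max(2, ceiling((s1 - s0) / step) + 1))
    top <- river_to_planar(land, ss, t1fun(ss))
    bot <- river_to_planar(land, rev(ss), t0fun(rev(ss)))
    coords <- rbind(top, bot, top[1, , drop = FALSE])
    list(apply(unname(coords), 1, as.list))
  }
  feats <- list()
  cl <- river_to_planar(land, s_grid, rep(0, length(s_grid)))
  feats[[1]] <- list(type = "Feature",
                     properties = list(role = "centerline"),
                     geometry = list(type = "LineString",
                                     coordinates = apply(unname(cl), 1,
                                                         as.list)))
  hw <- function(ss) tcw_profile(land, ss) / 2
  feats[[2]] <- list(type = "Feature",
                     properties = list(role = "channel"),
                     geometry = list(type = "Polygon",
                                     coordinates = ring(0, land$extent_m,
                                                        function(ss) -hw(ss),
                                                        hw, ds)))
  add_patches <- function(df, role, feats) {
    for (i in seq_len(nrow(df))) {
      feats[[length(feats) + 1]] <- list(
        type = "Feature", properties = list(role = role),
        geometry = list(type = "Polygon",
                        coordinates = ring(df$s0[i], df$s1[i],
                                           function(ss) rep(df$t0[i],
                                                            length(ss)),
                                           function(ss) rep(df$t1[i],
                                                            length(ss)),
                                           25)))
    }
    feats
  }
  feats <- add_patches(land$veg, "dense_veg", feats)
  feats <- add_patches(land$forest, "forest", feats)
  doc <- list(type = "FeatureCollection",
              riversel = list(
                extent_m = land$extent_m,
                seed = land$seed,
                spectral = land$spectral,
                veg = land$veg,
                forest = land$forest,
                dates = transform(land$dates, date = as.character(date)),
                config = unclass(land$config)),
              features = feats)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10,
                           pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a landscape written by [write_landscape_geojson()]
#'
#' Reconstructs the exact parametric landscape from the embedded
#' `riversel` metadata (the densified polygon features are display
#' geometry only).
#'
#' @param path GeoJSON path.
#' @return a `river_landscape`.
#' @export
read_landscape_geojson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  meta <- doc$riversel
  if (is.null(meta)) {
    stop("GeoJSON file lacks the embedded riversel metadata; only ",
         "landscapes written by write_landscape_geojson() can be read")
  }
  cfg <- meta$config
  class(cfg) <- "landscape_config"
  dates <- as.data.frame(meta$dates)
  dates$date <- as.Date(dates$date)
  structure(list(extent_m = meta$extent_m,
                 spectral = list(K = meta$spectral$K,
                                 omega = meta$spectral$omega,
                                 phase = meta$spectral$phase),
                 veg = as.data.frame(meta$veg),
                 forest = as.data.frame(meta$forest),
                 dates = dates,
                 config = cfg,
                 seed = as.integer(meta$seed)),
            class = "river_landscape")
}

# --- fit / ranking / response / validation artifacts -------------------

#' Serialize a fitted model to JSON
#' @param fit a `dcgam` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(model = fit$model$name,
              covariates = fit$model$covariates,
              smooth = fit$model$smooth,
              basis_dim = fit$basis_dim,
              coefficients = fit$coefficients,
              lambda = as.list(fit$lambda),
              edf = as.list(fit$edf), edf_total = fit$edf_total,
              loglik = fit$loglik,
              loglik_penalized = fit$loglik_penalized,
              aic = fit$aic, n_sets = fit$n_sets,
              converged = fit$converged,
              vcov = fit$vcov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Write a model ranking table as CSV (Model, Metrics, df, AIC, dAIC, weight)
#' @param ranking a [rank_models()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  out <- data.frame(Model = seq_len(nrow(ranking)),
                    Metrics = ranking$model,
                    df = signif(ranking$df, 6),
                    AIC = signif(ranking$aic, 8),
                    dAIC = signif(ranking$delta_aic, 6),
                    weight = signif(ranking$weight, 6),
                    selected = ranking$selected)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a response function as CSV plus a JSON peak/plateau summary
#' @param rf a [response_function()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the peak/plateau summary.
#' @export
write_response <- function(rf, csv_path = NULL, json_path = NULL) {
  pp <- peak_and_plateau(rf)
  if (!is.null(csv_path)) {
    out <- data.frame(covariate = attr(rf, "covariate"),
                      grid = signif(rf$grid, 6),
                      ratio = signif(rf$ratio, 6),
                      lo = signif(rf$ci_low, 6),
                      hi = signif(rf$ci_high, 6))
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(covariate = attr(rf, "covariate"),
                              peak_value = unname(pp["peak_value"]),
                              plateau_low = unname(pp["plateau_low"])),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(pp)
}

#' Write a validation result as JSON (plus optional per-replicate slopes)
#' @param vr a [validate_model()] result.
#' @param json_path output path for the summary.
#' @param slopes_csv optional CSV path for the per-replicate slopes.
#' @return `json_path`, invisibly.
#' @export
write_validation_json <- function(vr, json_path, slopes_csv = NULL) {
  jsonlite::write_json(list(mean_slope = vr$mean_slope,
                            ci95 = vr$ci95, verdict = vr$verdict,
                            n_reps = vr$n_reps, n_bins = vr$n_bins,
                            n_skipped = vr$n_skipped, seed = vr$seed),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(slopes_csv)) {
    utils::write.csv(data.frame(rep = seq_along(vr$slopes),
                                slope = signif(vr$slopes, 6)),
                     slopes_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
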