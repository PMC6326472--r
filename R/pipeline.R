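#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end run: the landscape (generator
#' parameters or a GeoJSON path), the generating truth, choice-set sizes,
#' the candidate model list, fitting and validation settings.
#'
#' @param seed master integer seed; every stage derives its own stream.
#' @param landscape a [landscape_config()], a `river_landscape`, or a path
#'   to a GeoJSON written by [write_landscape_geojson()].
#' @param truth a [selection_spec()] describing the generating selection
#'   surface.
#' @param n_use,n_avail stopovers and available points per choice set.
#' @param window_km availability half-window in km (16 each side).
#' @param basis_dim spline basis dimension (default 4).
#' @param models list of [candidate_model()]s (default
#'   [riverine_model_list()]).
#' @param cor_threshold collinearity screen threshold.
#' @param n_reps,n_bins,train_frac validation settings.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       landscape = landscape_config(),
                       truth = selection_spec(),
                       n_use = 85, n_avail = 20, window_km = 16,
                       basis_dim = 4,
                       models = riverine_model_list(),
                       cor_threshold = 0.6,
                       n_reps = 1000, n_bins = 20, train_frac = 2 / 3) {
  stopifnot(n_use >= 1, n_avail >= 1, n_reps >= 1, n_bins >= 2,
            train_frac > 0, train_frac < 1, window_km > 0, basis_dim >= 3)
  if (is.character(landscape) && !file.exists(landscape)) {
    stop("landscape file does not exist: ", landscape)
  }
  structure(as.list(environment()), class = "run_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[riversel] stage=%s %s", stage, paste0(...)))
}

#' Run the full habitat-selection pipeline
#'
#' simulate (or load) -> habitat metrics -> choice sets -> collinearity
#' screen -> fit all admissible candidates (with the linear fallback) ->
#' AIC ranking -> response functions of the selected model -> calibration
#' validation.  All artifacts (choices CSV, landscape GeoJSON, ranking
#' CSV, per-covariate response CSV/JSON, validation JSON, run manifest)
#' are written under `out_dir`; on failure a `FAILED` marker file naming
#' the stage is left beside any partial outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`landscape`,
#'   `choices`, `screen`, `fits`, `ranking`, `responses`, `validation`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "init"
  res <- list()
  tryCatch({
    stage <- "landscape"
    land <- config$landscape
    if (is.character(land)) {
      land <- read_landscape_geojson(land)
    } else if (inherits(land, "landscape_config")) {
      land <- generate_landscape(land, derive_seed(config$seed, "land"))
    }
    stopifnot(inherits(land, "river_landscape"))
    log_stage(stage, "extent_km=", land$extent_m / 1000)
    write_landscape_geojson(land, file.path(out_dir, "landscape.geojson"))

    stage <- "simulate"
    truth <- config$truth
    truth$n_use <- config$n_use
    truth$n_avail <- config$n_avail
    truth$window_m <- config$window_km * 1000
    choices <- simulate_stopovers(land, truth,
                                  derive_seed(config$seed, "sim"))
    log_stage(stage, "sets=", length(unique(choices$set_id)),
              " avail_rows=", sum(choices$used == 0))
    write_choice_csv(choices, file.path(out_dir, "choices.csv"))

    stage <- "screen"
    scr <- screen_collinearity(choices, config$models,
                               config$cor_threshold)
    log_stage(stage, "admissible=", length(scr$admissible),
              " rejected=", nrow(scr$rejected))

    stage <- "fit"
    fits <- lapply(scr$admissible, function(m) {
      f <- fit_dcgam(choices, m, basis_dim = config$basis_dim)
      linear_fallback(f)
    })
    log_stage(stage, "models_fit=", length(fits))

    stage <- "rank"
    ranking <- rank_models(fits)
    write_ranking_csv(ranking, file.path(out_dir, "ranking.csv"))
    sel_name <- attr(ranking, "selected_model")
    sel_fit <- fits[[which(vapply(fits, function(f) f$model$name, "") ==
                             sel_name)]]
    log_stage(stage, "selected=", sel_name)

    stage <- "respond"
    responses <- list()
    for (cv in sel_fit$model$covariates) {
      rf <- response_function(sel_fit, cv, choices)
      write_response(rf,
                     file.path(out_dir, paste0("response_", cv, ".csv")),
                     file.path(out_dir, paste0("response_", cv, ".json")))
      responses[[cv]] <- rf
    }

    stage <- "validate"
    vr <- validate_model(choices, sel_fit$model, n_reps = config$n_reps,
                         train_frac = config$train_frac,
                         n_bins = config$n_bins,
                         seed = derive_seed(config$seed, "validate"),
                         basis_dim = config$basis_dim)
    write_validation_json(vr, file.path(out_dir, "validation.json"),
                          file.path(out_dir, "slopes.csv"))
    log_stage(stage, "verdict=", vr$verdict)

    stage <- "manifest"
    manifest <- list(
      package = "riversel",
      version = as.character(utils::packageVersion("riversel")),
      seed = config$seed,
      n_use = config$n_use, n_avail = config$n_avail,
      n_sets = length(unique(choices$set_id)),
      n_avail_rows = sum(choices$used == 0),
      window_km = config$window_km, basis_dim = config$basis_dim,
      models = vapply(config$models, function(m) m$name, ""),
      selected_model = sel_name,
      verdict = vr$verdict,
      config_hash = derive_seed(config$seed, "manifest",
                                length(config$models), config$n_use,
                                config$n_avail))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    res <- list(landscape = land, choices = choices, screen = scr,
                fits = fits, ranking = ranking, responses = responses,
                validation = vr)
    invisible(res)
  }, error = function(e) {
    writeLines(paste0("stage=", stage, " error=", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages and share the CSV/GeoJSON/JSON
#' contracts so that each stage is independently scriptable:
#' `simulate`, `metrics`, `choicesets`, `fit`, `rank`, `respond`,
#' `validate`, `all`.  Invoke via the `exec/riversel` script or
#' `Rscript -e 'riversel::riversel_cli()' <cmd> ...`.
#'
#' @param argv character vector of arguments (defaults to the command
#'   line).
#' @return exit status 0 on success (invisibly); errors propagate.
#' @export
riversel_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    stop("usage: riversel <simulate|metrics|choicesets|fit|rank|respond|",
         "validate|all> [--key value ...]")
  }
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  need <- function(key) {
    v <- opts[[key]]
    if (is.null(v)) stop("missing required option --", key, " for ", cmd)
    v
  }
  num <- function(key, default = NULL) {
    v <- opts[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  get_model <- function() {
    nm <- need("model")
    all_models <- c(riverine_model_list(), corridor_model_list())
    hit <- Filter(function(m) m$name == nm, all_models)
    if (length(hit)) return(hit[[1]])
    candidate_model(nm, strsplit(nm, "+", fixed = TRUE)[[1]])
  }
  switch(cmd,
    simulate = {
      seed <- as.integer(need("seed"))
      out <- need("out-dir")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      land <- generate_landscape(landscape_config(), derive_seed(seed, "land"))
      spec <- selection_spec(n_use = num("n-use", 85),
                             n_avail = num("n-avail", 20))
      ch <- simulate_stopovers(land, spec, derive_seed(seed, "sim"))
      write_landscape_geojson(land, file.path(out, "landscape.geojson"))
      write_choice_csv(ch, file.path(out, "choices.csv"))
    },
    metrics = {
      land <- read_landscape_geojson(need("landscape"))
      pts <- utils::read.csv(need("points"))
      met <- attach_metrics(land, pts$s, pts$t,
                            num("discharge", exp(land$config$discharge_meanlog)))
      utils::write.csv(cbind(pts, signif(met, 6)), need("out"),
                       row.names = FALSE, quote = FALSE)
    },
    choicesets = {
      land <- read_landscape_geojson(need("landscape"))
      pts <- utils::read.csv(need("use-points"))
      ch <- build_choice_sets(pts, land, n_avail = num("n-avail", 20),
                              seed = as.integer(need("seed")))
      write_choice_csv(ch, need("out"))
    },
    fit = {
      ch <- read_choice_csv(need("choices"))
      fit <- linear_fallback(fit_dcgam(ch, get_model(),
                                       basis_dim = num("basis-dim", 4)))
      write_fit_json(fit, need("out"))
    },
    rank = {
      ch <- read_choice_csv(need("choices"))
      scr <- screen_collinearity(ch, riverine_model_list())
      fits <- lapply(scr$admissible, function(m)
        linear_fallback(fit_dcgam(ch, m, basis_dim = num("basis-dim", 4))))
      write_ranking_csv(rank_models(fits), need("out"))
    },
    respond = {
      ch <- read_choice_csv(need("choices"))
      model <- get_model()
      fit <- linear_fallback(fit_dcgam(ch, model,
                                       basis_dim = num("basis-dim", 4)))
      for (cv in model$covariates) {
        rf <- response_function(fit, cv, ch)
        write_response(rf, paste0(need("out-prefix"), cv, ".csv"),
                       paste0(need("out-prefix"), cv, ".json"))
      }
    },
    validate = {
      ch <- read_choice_csv(need("choices"))
      vr <- validate_model(ch, get_model(), n_reps = num("n-reps", 1000),
                           n_bins = num("n-bins", 20),
                           seed = as.integer(need("seed")))
      write_validation_json(vr, need("out"))
    },
    all = {
      cfg <- run_config(seed = as.integer(need("seed")),
                        n_use = num("n-use", 85),
                        n_avail = num("n-avail", 20),
                        n_reps = num("n-reps", 1000))
      run_pipeline(cfg, need("out-dir"))
    },
    stop("unknown subcommand '", cmd, "'")
  )
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}
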