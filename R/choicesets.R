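#' Assemble use-availability choice sets around observed use points
#'
#' For each use point, `n_avail` available points are sampled uniformly by
#' area within the roostable wetted channel of a river reach centered on
#' the use location and extending `window_m` up- and downstream (default
#' 16 km each way, a 32-km reach).  Window distance is measured along the
#' centerline, and windows reaching past a landscape end are clipped (with
#' a message).  The use location is always a member of its own choice set.
#'
#' @param use_points data.frame with columns `s`, `t` (curvilinear
#'   coordinates, m) and optionally `date`, `season`, `discharge_cms`; if
#'   flow information is missing a date is drawn per set from the
#'   landscape's date table.
#' @param land a `river_landscape`.
#' @param n_avail available points per use point (default 20).
#' @param seed integer seed.
#' @param window_m half-window along the river (m).
#' @return a `choice_data` data.frame; `n_use * n_avail` available rows.
#' @export
build_choice_sets <- function(use_points, land, n_avail = 20, seed = 1L,
                              window_m = 16000) {
  stopifnot(inherits(land, "river_landscape"), n_avail >= 1,
            all(c("s", "t") %in% names(use_points)))
  n_use <- nrow(use_points)
  if (n_use < 1) stop("need at least one use point")
  w <- tcw_profile(land, use_points$s)
  if (any(abs(use_points$t) >= w / 2)) {
    stop("use point(s) outside the channel polygon")
  }
  have_flow <- all(c("date", "season", "discharge_cms") %in%
                     names(use_points))
  if (!have_flow) {
    idx <- with_seed(derive_seed(seed, "cs-dates"),
                     sample.int(nrow(land$dates), n_use, replace = TRUE))
    use_points$date <- as.character(land$dates$date[idx])
    use_points$season <- land$dates$season[idx]
    use_points$discharge_cms <- land$dates$discharge_cms[idx]
  }
  rows <- vector("list", n_use)
  clipped <- 0L
  for (i in seq_len(n_use)) {
    lo <- use_points$s[i] - window_m
    hi <- use_points$s[i] + window_m
    if (lo < 0 || hi > land$extent_m) {
      clipped <- clipped + 1L
      lo <- max(0, lo)
      hi <- min(land$extent_m, hi)
    }
    av <- sample_inchannel(land, lo, hi, n_avail,
                           derive_seed(seed, "cs-points", i))
    s_all <- c(use_points$s[i], av[, "s"])
    t_all <- c(use_points$t[i], av[, "t"])
    met <- attach_metrics(land, s_all, t_all, use_points$discharge_cms[i])
    rows[[i]] <- data.frame(
      set_id = i,
      alt_id = seq_len(n_avail + 1L),
      used = as.integer(seq_len(n_avail + 1L) == 1L),
      x_m = s_all,
      met,
      season = use_points$season[i],
      date = as.character(use_points$date[i]),
      row.names = NULL)
  }
  if (clipped > 0) {
    message(clipped, " availability window(s) clipped at a landscape end")
  }
  out <- do.call(rbind, rows)
  attr(out, "window_m") <- window_m
  class(out) <- c("choice_data", "data.frame")
  out
}

#' Candidate model specification
#'
#' @param name model label.
#' @param covariates character vector of covariate names among `UOCW`,
#'   `TCW`, `UFCW`, `NF`, `UD`, `DIS` (empty for the null model).
#' @param smooth logical per covariate: penalized-spline smooth (default)
#'   or parametric linear term.
#' @return list of class `candidate_model`.
#' @export
candidate_model <- function(name, covariates = character(0),
                            smooth = rep(TRUE, length(covariates))) {
  stopifnot(length(smooth) == length(covariates))
  known <- names(covariate_columns())
  bad <- setdiff(covariates, known)
  if (length(bad)) {
    stop("model '", name, "' names unknown covariate(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = name, covariates = covariates, smooth = smooth),
            class = "candidate_model")
}

# map model covariate names to choice-data column names
covariate_columns <- function() {
  c(UOCW = "uocw_m", TCW = "tcw_m", UFCW = "ufcw_m", NF = "nf_m",
    UD = "ud_cms_per_m", DIS = "dis_cms_per_m")
}

#' The a-priori in-channel candidate model list (14 models incl. null)
#'
#' The full model set screened for the main riverine analysis: single
#' metrics, and combinations of channel-openness and flow metrics that are
#' not expected to be collinear.
#'
#' @return list of `candidate_model`s.
#' @export
riverine_model_list <- function() {
  mk <- candidate_model
  list(
    mk("NULL"),
    mk("UOCW", "UOCW"),
    mk("TCW", "TCW"),
    mk("NF", "NF"),
    mk("UFCW", "UFCW"),
    mk("UD", "UD"),
    mk("DIS", "DIS"),
    mk("UOCW+NF", c("UOCW", "NF")),
    mk("UOCW+UD", c("UOCW", "UD")),
    mk("UOCW+DIS", c("UOCW", "DIS")),
    mk("TCW+UOCW", c("TCW", "UOCW")),
    mk("TCW+NF+UOCW", c("TCW", "NF", "UOCW")),
    mk("UOCW+NF+UD", c("UOCW", "NF", "UD")),
    mk("UOCW+NF+DIS", c("UOCW", "NF", "DIS")))
}

#' The reduced corridor-wide candidate model list (4 models incl. null)
#'
#' Null, each openness driver alone, and both together -- the list used
#' when only unobstructed channel width and nearest-forest distance are
#' carried forward.
#'
#' @return list of `candidate_model`s.
#' @export
corridor_model_list <- function() {
  list(candidate_model("NULL"),
       candidate_model("UOCW", "UOCW"),
       candidate_model("NF", "NF"),
       candidate_model("UOCW+NF", c("UOCW", "NF")))
}

#' Screen candidate models for collinear covariate pairs
#'
#' Computes the Pearson correlation matrix of the six habitat covariates
#' over all rows (used and available pooled) and rejects any candidate
#' model containing a covariate pair with `|r|` above the threshold.
#' Covariates that are constant (correlation undefined) disqualify every
#' model containing them.
#'
#' @param data a `choice_data` data.frame.
#' @param models list of [candidate_model()]s.
#' @param threshold absolute-correlation cutoff (default 0.6).
#' @return list with `admissible` (models), `rejected` (data.frame of
#'   model/reason), and `cor_matrix`.
#' @export
screen_collinearity <- function(data, models, threshold = 0.6) {
  if (nrow(data) < 3) stop("need at least 3 rows to estimate correlations")
  cols <- covariate_columns()
  have <- cols[cols %in% names(data)]
  mat <- as.matrix(data[, have, drop = FALSE])
  constant <- apply(mat, 2, function(v) stats::sd(v) == 0 || !all(is.finite(v)))
  cm <- suppressWarnings(stats::cor(mat))
  dimnames(cm) <- list(names(have), names(have))
  admissible <- list()
  rejected <- data.frame(model = character(0), reason = character(0))
  for (m in models) {
    covs <- m$covariates
    if (any(constant[cols[covs]])) {
      rejected <- rbind(rejected, data.frame(
        model = m$name,
        reason = paste0("constant covariate: ",
                        paste(covs[constant[cols[covs]]], collapse = ", "))))
      next
    }
    bad_pair <- NULL
    if (length(covs) > 1) {
      pr <- utils::combn(covs, 2)
      for (j in seq_len(ncol(pr))) {
        r <- cm[pr[1, j], pr[2, j]]
        if (!is.finite(r) || abs(r) > threshold) {
          bad_pair <- paste0(pr[1, j], "~", pr[2, j], " (r = ",
                             signif(r, 3), ")")
          break
        }
      }
    }
    if (is.null(bad_pair)) {
      admissible <- c(admissible, list(m))
    } else {
      rejected <- rbind(rejected,
                        data.frame(model = m$name, reason = bad_pair))
    }
  }
  list(admissible = admissible, rejected = rejected, cor_matrix = cm)
}

#' Split choice sets into training and test partitions
#'
#' Splits by whole choice set (never by row); the training count is the
#' number of sets times `train_frac`, rounded to the nearest integer
#' (235 sets at 2/3 gives 157 training and 78 test sets).
#'
#' @param data a `choice_data` data.frame (or a vector of set ids).
#' @param train_frac training fraction (default 2/3).
#' @param seed integer seed.
#' @return list with `train` and `test` (same type as the input).
#' @export
split_train_test <- function(data, train_frac = 2 / 3, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  ids <- if (is.data.frame(data)) unique(data$set_id) else unique(data)
  n <- length(ids)
  if (n < 3) stop("need at least 3 choice sets to split")
  n_train <- round(n * train_frac)
  tr_ids <- with_seed(seed, sample(ids, n_train))
  if (is.data.frame(data)) {
    list(train = data[data$set_id %in% tr_ids, , drop = FALSE],
         test = data[!data$set_id %in% tr_ids, , drop = FALSE])
  } else {
    list(train = ids[ids %in% tr_ids], test = ids[!ids %in% tr_ids])
  }
}
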