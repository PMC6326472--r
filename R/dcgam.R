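#' Conditional (within-choice-set) multinomial log-likelihood
#'
#' The discrete-choice likelihood is the product over choice sets of the
#' chosen alternative's weight divided by the summed weights of all
#' alternatives in the set, with weight `w = exp(eta)`.  Computed with a
#' log-sum-exp stabilisation so it is finite for any finite linear
#' predictor.
#'
#' @param eta per-row linear predictor.
#' @param set_id per-row choice-set identifier.
#' @param used per-row 0/1 flag; exactly one 1 per set.
#' @return the scalar log-likelihood.
#' @export
conditional_loglik <- function(eta, set_id, used) {
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor in set ",
         set_id[which(!is.finite(eta))[1]])
  }
  gi <- match(set_id, unique(set_id))
  ones <- rowsum(as.numeric(used), gi)
  if (any(ones != 1)) {
    stop("choice set ", unique(set_id)[which(ones != 1)[1]],
         " does not have exactly one used alternative")
  }
  M <- vapply(split(eta, gi), max, numeric(1))
  denom <- rowsum(exp(eta - M[gi]), gi)
  sum(eta[used == 1]) - sum(log(denom) + M)
}

# --- internal fitting machinery ---------------------------------------

# precompute per-set row indices and validate the choice structure
choice_index <- function(data) {
  ids <- unique(data$set_id)
  gi <- match(data$set_id, ids)
  idx <- split(seq_len(nrow(data)), gi)
  used <- as.numeric(data$used)
  ones <- rowsum(used, gi)
  if (any(ones != 1)) {
    stop("choice set ", ids[which(ones != 1)[1]],
         " does not have exactly one used alternative")
  }
  list(gi = gi, idx = idx, used = used, n_sets = length(ids),
       set_sizes = lengths(idx), ids = ids)
}

# design matrices, penalties and coefficient blocks for a candidate model
build_terms <- function(data, model, basis_dim) {
  cols <- covariate_columns()
  terms <- list()
  X <- NULL
  blocks <- list()
  p0 <- 0L
  for (j in seq_along(model$covariates)) {
    cv <- model$covariates[j]
    x <- data[[cols[cv]]]
    if (is.null(x)) stop("covariate column '", cols[cv], "' missing")
    if (any(!is.finite(x))) {
      stop("non-finite covariate ", cv, " in set ",
           data$set_id[which(!is.finite(x))[1]])
    }
    if (isTRUE(model$smooth[j])) {
      b <- spline_basis(x, basis_dim)
      Xj <- b$design
      terms[[cv]] <- list(name = cv, type = "smooth", basis = b,
                          penalty = b$penalty)
    } else {
      ctr <- mean(x)
      Xj <- matrix(x - ctr, ncol = 1)
      terms[[cv]] <- list(name = cv, type = "linear", center = ctr,
                          penalty = NULL)
    }
    blocks[[cv]] <- p0 + seq_len(ncol(Xj))
    p0 <- p0 + ncol(Xj)
    X <- if (is.null(X)) Xj else cbind(X, Xj)
  }
  list(terms = terms, X = X, blocks = blocks, p = p0)
}

# block-diagonal penalty matrix for the full coefficient vector
penalty_matrix <- function(tm, lambda) {
  S <- matrix(0, tm$p, tm$p)
  for (nm in names(tm$terms)) {
    t_ <- tm$terms[[nm]]
    if (t_$type == "smooth") {
      S[tm$blocks[[nm]], tm$blocks[[nm]]] <- lambda[nm] * t_$penalty
    }
  }
  S
}

# penalized Newton for the conditional multinomial likelihood
pen_newton <- function(X, ci, S_pen, beta0 = NULL,
                       tol = 1e-8, max_iter = 200L) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  used <- ci$used
  gi <- ci$gi
  ll_parts <- function(beta) {
    eta <- drop(X %*% beta)
    M <- vapply(ci$idx, function(ii) max(eta[ii]), numeric(1))
    e <- exp(eta - M[gi])
    denom <- drop(rowsum(e, gi))
    P <- e / denom[gi]
    ll <- sum(eta[used == 1]) - sum(log(denom) + M)
    list(ll = ll, P = P)
  }
  cur <- ll_parts(beta)
  pen_ll <- function(beta, ll) ll - 0.5 * drop(crossprod(beta, S_pen %*% beta))
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  grad_norm <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    PX <- cur$P * X
    grad <- drop(crossprod(X, used - cur$P)) - drop(S_pen %*% beta)
    I_unpen <- crossprod(X, PX) - crossprod(rowsum(PX, gi))
    H <- I_unpen + S_pen
    grad_norm <- max(abs(grad))
    if (grad_norm < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(H, grad),
                     error = function(e) solve(H + diag(1e-8, ncol(H)), grad))
    f0 <- pen_ll(beta, cur$ll)
    alpha <- 1
    accepted <- FALSE
    while (alpha >= 1e-10) {
      beta_new <- beta + alpha * step
      nxt <- ll_parts(beta_new)
      if (is.finite(nxt$ll) && pen_ll(beta_new, nxt$ll) > f0 - 1e-12) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break  # no ascent direction left; report as-is
    beta <- beta_new
    cur <- nxt
    if (sqrt(sum(beta^2)) > 1e4) {  # complete separation: unbounded drift
      diverged <- TRUE
      break
    }
  }
  PX <- cur$P * X
  I_unpen <- crossprod(X, PX) - crossprod(rowsum(PX, gi))
  list(beta = beta, loglik = cur$ll, I_unpen = I_unpen,
       H_pen = I_unpen + S_pen,
       converged = converged && !diverged, separation = diverged,
       iterations = iter, grad_norm = grad_norm)
}

edf_from_fit <- function(fit_raw, tm) {
  A <- tryCatch(solve(fit_raw$H_pen, fit_raw$I_unpen),
                error = function(e) {
                  warning("singular penalized information; using pseudo-inverse")
                  MASS_ginv(fit_raw$H_pen) %*% fit_raw$I_unpen
                })
  d <- diag(A)
  per_term <- vapply(tm$blocks, function(b) sum(d[b]), numeric(1))
  list(per_term = per_term, total = sum(d))
}

# small pseudo-inverse (avoids a MASS dependency)
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

gcv_score <- function(loglik, edf_total, n_sets) {
  n_sets * (-2 * loglik) / (n_sets - edf_total)^2
}

#' Default smoothing-parameter grid
#'
#' 25 log-spaced values spanning 1e-4 to 1e6.
#' @return numeric vector.
#' @export
lambda_grid_default <- function() 10^seq(-4, 6, length.out = 25)

#' Fit a penalized-spline discrete-choice model
#'
#' Maximizes the conditional multinomial (use-availability) likelihood by
#' penalized Newton iteration; each smooth term's smoothing parameter is
#' chosen by minimizing a generalized-cross-validation style score
#' `n (-2 loglik) / (n - edf)^2` (n = number of choice sets) over a
#' log-spaced grid, by coordinate-wise sweeps when the model has more than
#' one smooth term.  The returned AIC is
#' `-2 * (unpenalized loglik at the penalized optimum) + 2 * total EDF`.
#'
#' @param data a `choice_data` data.frame.
#' @param model a [candidate_model()].
#' @param basis_dim raw basis dimension per smooth (default 4, i.e. fewer
#'   than four effective degrees of freedom per term after centering).
#' @param lambda optional fixed smoothing parameters (named by covariate or
#'   a single value recycled); skips the grid search.
#' @param lambda_grid grid for the search (default
#'   [lambda_grid_default()]).
#' @param control list: `tol` (gradient sup-norm, default 1e-8),
#'   `max_iter` (default 200), `sweeps` (coordinate sweeps, default 2).
#' @return an object of class `dcgam`.
#' @export
fit_dcgam <- function(data, model, basis_dim = 4, lambda = NULL,
                      lambda_grid = lambda_grid_default(),
                      control = list()) {
  stopifnot(inherits(model, "candidate_model"))
  ctl <- utils::modifyList(list(tol = 1e-8, max_iter = 200L, sweeps = 2L),
                           control)
  ci <- choice_index(data)
  n <- ci$n_sets

  if (length(model$covariates) == 0) {  # null model: forced likelihood
    ll <- -sum(log(ci$set_sizes))
    return(structure(list(model = model, terms = list(), blocks = list(),
                          coefficients = numeric(0),
                          lambda = numeric(0),
                          edf = numeric(0), edf_total = 0,
                          loglik = ll, loglik_penalized = ll,
                          aic = -2 * ll, vcov = matrix(0, 0, 0),
                          converged = TRUE, n_sets = n,
                          gcv = gcv_score(ll, 0, n),
                          basis_dim = basis_dim, data = data),
                     class = "dcgam"))
  }

  tm <- build_terms(data, model, basis_dim)
  smooth_names <- names(tm$terms)[vapply(tm$terms, function(t_)
    t_$type == "smooth", logical(1))]

  lam <- stats::setNames(rep(1, length(smooth_names)), smooth_names)
  if (!is.null(lambda)) {
    if (is.null(names(lambda))) {
      lam[] <- rep_len(lambda, length(lam))
    } else {
      lam[names(lambda)] <- lambda
    }
  }

  fit_at <- function(lam, beta0) {
    pen_newton(tm$X, ci, penalty_matrix(tm, lam), beta0,
               tol = ctl$tol, max_iter = ctl$max_iter)
  }

  beta <- numeric(tm$p)
  raw <- fit_at(lam, beta)
  beta <- raw$beta
  if (is.null(lambda) && length(smooth_names)) {
    best_score <- gcv_score(raw$loglik, edf_from_fit(raw, tm)$total, n)
    for (sweep in seq_len(ctl$sweeps)) {
      changed <- FALSE
      for (nm in smooth_names) {
        for (lv in lambda_grid) {
          if (lv == lam[nm]) next
          lam_try <- lam
          lam_try[nm] <- lv
          cand <- fit_at(lam_try, beta)
          sc <- gcv_score(cand$loglik, edf_from_fit(cand, tm)$total, n)
          if (is.finite(sc) && sc < best_score - 1e-12) {
            best_score <- sc
            lam <- lam_try
            raw <- cand
            beta <- cand$beta
            changed <- TRUE
          }
        }
      }
      if (!changed || length(smooth_names) == 1) break
    }
  }

  edf <- edf_from_fit(raw, tm)
  vcov <- tryCatch(solve(raw$H_pen),
                   error = function(e) MASS_ginv(raw$H_pen))
  structure(list(model = model, terms = tm$terms, blocks = tm$blocks,
                 coefficients = raw$beta, lambda = lam,
                 edf = edf$per_term, edf_total = edf$total,
                 loglik = raw$loglik,
                 loglik_penalized = raw$loglik -
                   0.5 * drop(crossprod(raw$beta,
                                        penalty_matrix(tm, lam) %*% raw$beta)),
                 aic = -2 * raw$loglik + 2 * edf$total,
                 vcov = vcov, converged = raw$converged,
                 separation = raw$separation,
                 iterations = raw$iterations, n_sets = n,
                 gcv = gcv_score(raw$loglik, edf$total, n),
                 basis_dim = basis_dim, data = data),
            class = "dcgam")
}

#' @export
print.dcgam <- function(x, ...) {
  cat("<dcgam> model ", x$model$name, ": ", x$n_sets, " choice sets\n",
      sep = "")
  cat("  loglik ", signif(x$loglik, 8), ", total EDF ",
      signif(x$edf_total, 4), ", AIC ", signif(x$aic, 8), "\n", sep = "")
  if (length(x$edf)) {
    for (nm in names(x$edf)) {
      t_ <- x$terms[[nm]]
      cat("  ", nm, " [", t_$type, "] edf = ", signif(x$edf[nm], 4),
          if (t_$type == "smooth")
            paste0(", lambda = ", signif(x$lambda[nm], 3)) else "",
          "\n", sep = "")
    }
  }
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' Linear predictor for new data
#'
#' @param object a `dcgam` fit.
#' @param newdata data.frame with the model's covariate columns (defaults
#'   to the fitting data).
#' @param ... unused.
#' @return numeric vector of per-row linear predictors.
#' @export
predict.dcgam <- function(object, newdata = object$data, ...) {
  if (!length(object$terms)) return(rep(0, nrow(newdata)))
  cols <- covariate_columns()
  eta <- rep(0, nrow(newdata))
  for (nm in names(object$terms)) {
    t_ <- object$terms[[nm]]
    x <- newdata[[cols[nm]]]
    if (is.null(x)) stop("covariate column '", cols[nm], "' missing")
    Xj <- if (t_$type == "smooth") spline_eval(t_$basis, x)
          else matrix(x - t_$center, ncol = 1)
    eta <- eta + drop(Xj %*% object$coefficients[object$blocks[[nm]]])
  }
  eta
}

#' Effective degrees of freedom of a fit
#'
#' EDF is the trace of the matrix mapping the working response to the fit,
#' `(I_pen)^-1 I_unpen`, accumulated per term over that term's coefficient
#' block.  One EDF is a straight line; the unpenalized limit of a smooth
#' with `basis_dim = k` is `k - 1`.
#'
#' @param fit a `dcgam` fit.
#' @return list with `per_term` (named) and `total`.
#' @export
effective_df <- function(fit) {
  stopifnot(inherits(fit, "dcgam"))
  list(per_term = fit$edf, total = fit$edf_total)
}

#' Replace effectively linear smooths by parametric straight lines
#'
#' Any smooth term whose effective degrees of freedom are within `tol` of
#' one is refitted as a single-coefficient linear term (the smoothing
#' penalty has shrunk it to a straight line, so the spline machinery only
#' costs complexity); other terms keep their structure.  If no term
#' qualifies, the fit is returned unchanged.
#'
#' @param fit a `dcgam` fit.
#' @param tol tolerance around 1 (default 0.05).
#' @return a `dcgam` fit (refit or the input).
#' @export
linear_fallback <- function(fit, tol = 0.05) {
  stopifnot(inherits(fit, "dcgam"))
  if (!length(fit$terms)) return(fit)
  is_smooth <- vapply(fit$terms, function(t_) t_$type == "smooth",
                      logical(1))
  near_line <- is_smooth & abs(fit$edf - 1) <= tol
  if (!any(near_line)) return(fit)
  model <- fit$model
  model$smooth[match(names(which(near_line)), model$covariates)] <- FALSE
  fit_dcgam(fit$data, model, basis_dim = fit$basis_dim)
}
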