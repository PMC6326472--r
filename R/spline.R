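#' Penalized cubic regression spline basis for one smooth term
#'
#' Builds a natural cubic regression spline basis of dimension
#' `basis_dim`: the coefficients are the function values at `basis_dim`
#' knots placed at quantiles of the covariate, interpolated by a natural
#' cubic spline (zero second derivative beyond the end knots, linear
#' extrapolation).  The roughness penalty is the integrated squared
#' second derivative, a banded quadratic form in the knot values whose
#' null space holds exactly the constant and linear trends (rank
#' `basis_dim - 2`).
#'
#' The raw basis is a partition of unity (interpolating all-ones gives
#' the constant function), which makes the constant direction
#' unidentifiable inside a conditional (within-choice-set) likelihood;
#' the basis is therefore reparameterized onto the orthogonal complement
#' of the constant coefficient vector and its columns are centered to
#' mean zero over the supplied values.  The penalty null space then
#' contains exactly the linear trend, so the smooth shrinks to a straight
#' line (one effective degree of freedom) as the smoothing parameter
#' grows, and the unpenalized limit has `basis_dim - 1` degrees of
#' freedom.  The default `basis_dim = 4` caps the potential degrees of
#' freedom per term at three -- fewer than four, as appropriate for small
#' samples of use locations -- while the quantile knots keep the basis
#' flexible enough to represent saturating (rise-then-plateau) response
#' shapes.
#'
#' @param x covariate values used to place the knots and center the
#'   design (fit-time values).
#' @param basis_dim number of knots / raw basis functions (>= 3).
#' @param range numeric length-2 covariate range; values of `x` outside
#'   it are an error at fit time.
#' @return list of class `spline_basis` with elements `design`
#'   (n x (basis_dim - 1) centered identifiable design), `penalty`
#'   (matching roughness penalty), `raw` (n x basis_dim partition-of-unity
#'   basis), `penalty_raw`, plus knots and centering info for prediction.
#' @export
spline_basis <- function(x, basis_dim = 4, range = base::range(x)) {
  stopifnot(basis_dim >= 3, length(range) == 2)
  if (!(range[2] > range[1])) stop("degenerate covariate range")
  if (any(x < range[1] - 1e-9 | x > range[2] + 1e-9)) {
    stop("covariate values outside the basis range at fit time")
  }
  x <- pmin(pmax(x, range[1]), range[2])
  k <- as.integer(basis_dim)
  knots <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k),
                                  names = FALSE))
  if (length(knots) < k) {  # heavy ties: fall back to an even grid
    knots <- seq(range[1], range[2], length.out = k)
  }
  knots[1] <- range[1]
  knots[k] <- range[2]
  B <- cr_design(knots, x)
  S_raw <- cr_penalty(knots)
  # drop the constant coefficient direction (rowSums(B) == 1)
  Z <- qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
  X <- B %*% Z
  centers <- colMeans(X)
  X <- sweep(X, 2, centers)
  # rescale the penalty to unit magnitude so the smoothing-parameter grid
  # is unit-free (the raw penalty scales like 1/knot-spacing^3)
  S_z <- crossprod(Z, S_raw %*% Z)
  S_z <- S_z / mean(diag(S_z))
  structure(list(design = X,
                 penalty = S_z,
                 raw = B, penalty_raw = S_raw,
                 knots = knots, range = range, Z = Z, centers = centers,
                 basis_dim = k),
            class = "spline_basis")
}

# natural-cubic-spline cardinal basis: column j interpolates the j-th
# unit vector at the knots
cr_design <- function(knots, x) {
  k <- length(knots)
  B <- matrix(0, length(x), k)
  for (j in seq_len(k)) {
    e <- numeric(k)
    e[j] <- 1
    B[, j] <- stats::spline(knots, e, xout = x, method = "natural")$y
  }
  B
}

# integrated squared second derivative of a natural cubic spline as a
# quadratic form in the knot values: S = t(D) %*% solve(B) %*% D with the
# standard banded D (k-2 x k) and B (k-2 x k-2) matrices
cr_penalty <- function(knots) {
  k <- length(knots)
  h <- diff(knots)
  D <- matrix(0, k - 2, k)
  Bm <- matrix(0, k - 2, k - 2)
  for (i in seq_len(k - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    Bm[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) {
      Bm[i, i + 1] <- Bm[i + 1, i] <- h[i + 1] / 6
    }
  }
  crossprod(D, solve(Bm, D))
}

#' Evaluate a fitted spline basis at new covariate values
#'
#' Values outside the fitting range are clamped to it with a warning
#' (prediction-time behaviour; at fit time they are an error).
#'
#' @param basis a [spline_basis()].
#' @param x new covariate values.
#' @return design matrix on the identifiable centered parameterization.
#' @export
spline_eval <- function(basis, x) {
  r <- basis$range
  if (any(x < r[1] | x > r[2])) {
    warning("covariate values outside the basis range were clamped")
    x <- pmin(pmax(x, r[1]), r[2])
  }
  B <- cr_design(basis$knots, x)
  sweep(B %*% basis$Z, 2, basis$centers)
}
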