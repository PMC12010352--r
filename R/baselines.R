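#' Options for the reference solvers
#'
#' @param regularization nonnegative ridge parameter, expressed relative to
#'   the mean eigenvalue of the matrix being regularized (the sensor Gram
#'   matrix LL' for sLORETA, the data covariance for LCMV). Default 0.05.
#' @param mce_penalty nonnegative L1 penalty for MCE, relative to the largest
#'   absolute back-projected datum `max |L'y|` (so the useful range is (0, 1);
#'   1 or more yields the all-zero solution). Default 0.1.
#' @param mce_max_iter,mce_tol proximal-iteration controls for MCE.
#' @param mce_temporal `"per-sample"` (default; independent lasso per time
#'   sample) or `"pca"` (solve on the dominant temporal principal component
#'   and propagate its loadings).
#' @return list of class `snc_baseline_options`.
#' @export
baseline_options <- function(regularization = 0.05, mce_penalty = 0.1,
                             mce_max_iter = 2000L, mce_tol = 1e-8,
                             mce_temporal = c("per-sample", "pca")) {
  mce_temporal <- match.arg(mce_temporal)
  if (regularization < 0 || mce_penalty < 0) stop("options must be nonnegative")
  structure(list(regularization = regularization, mce_penalty = mce_penalty,
                 mce_max_iter = as.integer(mce_max_iter), mce_tol = mce_tol,
                 mce_temporal = mce_temporal),
            class = "snc_baseline_options")
}

#' sLORETA: standardized minimum-norm estimate
#'
#' Minimum-norm kernel `W = L' (L L' + eps I)^{-1}` with each voxel's estimate
#' standardized by the square root of the corresponding resolution-matrix
#' diagonal `(W L)_ii`. The standardization gives zero localization bias for a
#' single noiseless source as the regularization vanishes.
#'
#' @param data [sensor_dataset()].
#' @param lf [leadfield()].
#' @param opts [baseline_options()]; `regularization` scales the mean
#'   eigenvalue of LL', i.e. `eps = reg * tr(LL')/m`.
#' @return list with `power_map` (length n) and `xbar` (n x K standardized
#'   time courses).
#' @export
sloreta_solve <- function(data, lf, opts = baseline_options()) {
  stopifnot(inherits(data, "snc_dataset"), inherits(lf, "snc_leadfield"))
  L <- lf$gain
  m <- nrow(L)
  G <- sym(L %*% t(L))
  eps <- opts$regularization * sum(diag(G)) / m
  Ginv_L <- jitter_solve(G + diag(eps, m), L)        # (LL'+epsI)^{-1} L
  res_diag <- colSums(L * Ginv_L)                    # (WL)_ii = l_i'(LL'+eps)^{-1}l_i
  if (any(res_diag <= 0)) stop("non-positive resolution diagonal; rank-deficient LL' with eps = 0?")
  xbar <- (t(Ginv_L) %*% data$y) / sqrt(res_diag)    # W y, standardized
  list(power_map = rowMeans(xbar^2), xbar = xbar)
}

#' LCMV: linearly constrained minimum-variance beamformer
#'
#' Unit-gain spatial filter per voxel, `w_i = C^{-1} l_i / (l_i' C^{-1} l_i)`
#' with data covariance `C = (1/K) Y Y' + eps I`. The output power
#' `w_i' C w_i` is the minimum output variance subject to unit gain at
#' voxel i.
#'
#' @inheritParams sloreta_solve
#' @param opts [baseline_options()]; `regularization` scales the mean
#'   eigenvalue of C. With fewer samples than sensors and `regularization = 0`
#'   a warning is raised and a minimal ridge is forced.
#' @return list with `power_map`, `xbar`, and `weights` (m x n filter matrix).
#' @export
lcmv_solve <- function(data, lf, opts = baseline_options()) {
  stopifnot(inherits(data, "snc_dataset"), inherits(lf, "snc_leadfield"))
  L <- lf$gain
  m <- data$m
  C <- sym(data$y %*% t(data$y)) / data$K
  reg <- opts$regularization
  if (data$K < m && reg == 0) {
    warning("K < m with zero regularization: data covariance is singular; forcing a minimal ridge")
    reg <- 1e-8
  }
  C <- C + diag(reg * sum(diag(C)) / m, m)
  Cinv_L <- jitter_solve(C, L)
  denom <- colSums(L * Cinv_L)                       # l_i' C^{-1} l_i
  if (any(denom <= 0)) stop("non-positive beamformer denominator; C not PD")
  W <- sweep(Cinv_L, 2L, denom, "/")                 # w_i columns, unit gain
  xbar <- t(W) %*% data$y
  list(power_map = colSums(W * (C %*% W)), xbar = xbar, weights = W)
}

# Proximal gradient (FISTA) for min_x 0.5 ||y - L x||^2 + lambda ||x||_1.
# Y may have several columns; each is solved with the shared step size.
fista_lasso <- function(L, Y, lambda, max_iter = 2000L, tol = 1e-8) {
  Y <- as.matrix(Y)
  n <- ncol(L)
  step <- 1 / max(svd(L, nu = 0, nv = 0)$d[1]^2, .Machine$double.eps)
  X <- matrix(0, n, ncol(Y))
  Z <- X
  tk <- 1
  LtY <- t(L) %*% Y
  LtL <- t(L) %*% L
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    G <- LtL %*% Z - LtY
    Xn <- Z - step * G
    Xn <- sign(Xn) * pmax(abs(Xn) - step * lambda, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Xn + ((tk - 1) / tn) * (Xn - X)
    delta <- max(abs(Xn - X)) / max(max(abs(X)), 1e-12)
    X <- Xn
    tk <- tn
    if (delta < tol) { conv <- TRUE; break }
  }
  if (!conv) warning("MCE proximal iteration did not converge in ", max_iter,
                     " iterations; returning best iterate")
  X
}

#' MCE: minimum current estimate (L1-penalized inverse)
#'
#' Solves `min_x 0.5 ||y_k - L x||^2 + lambda ||x||_1` by FISTA, either
#' independently per time sample (default) or on the dominant temporal
#' principal component. The penalty is `opts$mce_penalty * max|L'Y|` so that a
#' relative penalty of 1 or more gives the all-zero solution.
#'
#' @inheritParams sloreta_solve
#' @return list with `power_map`, `xbar`, and `lambda` (the absolute penalty
#'   used).
#' @export
mce_solve <- function(data, lf, opts = baseline_options()) {
  stopifnot(inherits(data, "snc_dataset"), inherits(lf, "snc_leadfield"))
  L <- lf$gain
  lam_max <- max(abs(t(L) %*% data$y))
  lambda <- opts$mce_penalty * lam_max
  if (lambda <= 0 && lam_max > 0) stop("MCE penalty must be positive")
  if (opts$mce_temporal == "per-sample") {
    xbar <- fista_lasso(L, data$y, lambda, opts$mce_max_iter, opts$mce_tol)
  } else {
    sv <- svd(data$y, nu = 1, nv = 1)
    comp <- sv$u[, 1, drop = FALSE] * sv$d[1]        # dominant spatial pattern x amplitude
    xc <- fista_lasso(L, comp, opts$mce_penalty * max(abs(t(L) %*% comp)),
                      opts$mce_max_iter, opts$mce_tol)
    xbar <- xc %*% t(sv$v[, 1, drop = FALSE])
  }
  list(power_map = rowMeans(xbar^2), xbar = xbar, lambda = lambda)
}
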