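#' Model data covariance
#'
#' The marginal covariance of the sensor data under the linear-Gaussian
#' generative model y_k = L x_k + z_k with independent sources of variance
#' v_i and noise covariance Sigma_n:
#' \deqn{\Sigma_y = \Sigma_n + L \,\mathrm{diag}(v)\, L^\top.}
#'
#' @param lf [leadfield()] object (m x n).
#' @param v nonnegative length-n vector of per-voxel source variances.
#' @param noise [noise_model()] object (m x m).
#' @return Symmetric positive-definite m x m matrix (explicitly symmetrized).
#' @export
compute_model_covariance <- function(lf, v, noise) {
  stopifnot(inherits(lf, "snc_leadfield"), inherits(noise, "snc_noise_model"))
  v <- as.numeric(v)
  if (length(v) != lf$n) stop("length(v) must equal the number of voxels n")
  if (noise$m != lf$m) stop("noise covariance dimension must equal the sensor count m")
  stopifnot_finite(v, "v")
  if (any(v < 0)) stop("source variances must be nonnegative")
  act <- which(v > 0)
  S <- noise$covariance
  if (length(act) > 0L) {
    La <- lf$gain[, act, drop = FALSE]
    S <- S + La %*% (v[act] * t(La))
  }
  sym(S)
}

#' Posterior source estimates
#'
#' Posterior mean of the source activity given the data under the Gaussian
#' model: \eqn{\bar x_k = \mathrm{diag}(v) L^\top \Sigma_y^{-1} y_k}. Voxels
#' with zero prior variance have exactly zero posterior mean and are excluded
#' from the (optional) posterior precision \eqn{\Gamma = \Phi + L^\top
#' \Lambda L}, which is only defined where the prior variance is positive.
#'
#' @param data [sensor_dataset()].
#' @param lf [leadfield()].
#' @param v nonnegative length-n vector of source variances.
#' @param noise [noise_model()].
#' @param return_precision if `TRUE`, also return the posterior precision over
#'   the active voxels (those with v > 0).
#' @return list with `xbar` (n x K posterior means), and when requested
#'   `posterior_precision` (n_active x n_active) plus `active` (their indices).
#' @export
compute_posterior_sources <- function(data, lf, v, noise, return_precision = FALSE) {
  stopifnot(inherits(data, "snc_dataset"), inherits(lf, "snc_leadfield"),
            inherits(noise, "snc_noise_model"))
  v <- as.numeric(v)
  if (length(v) != lf$n) stop("length(v) must equal n")
  if (data$m != lf$m) stop("data and lead-field disagree on sensor count")
  Sigma_y <- compute_model_covariance(lf, v, noise)
  SyinvY <- jitter_solve(Sigma_y, data$y)           # m x K
  xbar <- v * (t(lf$gain) %*% SyinvY)               # diag(v) L' Sy^{-1} Y
  out <- list(xbar = xbar)
  if (return_precision) {
    act <- which(v > 0)
    La <- lf$gain[, act, drop = FALSE]
    Lam <- noise_precision(noise)
    out$posterior_precision <- sym(diag(1 / v[act], length(act)) + t(La) %*% Lam %*% La)
    out$active <- act
  }
  out
}

#' Champagne marginal-likelihood cost
#'
#' The (negative log-marginal-likelihood shaped) cost minimized by the
#' evidence-maximization updates:
#' \deqn{F = \log|\Sigma_y| + \frac1K \sum_k y_k^\top \Sigma_y^{-1} y_k.}
#' Up to the affine constant m log(2 pi) this equals -2/K times the joint
#' Gaussian log-density of the K data columns.
#'
#' @param data [sensor_dataset()].
#' @param Sigma_y symmetric positive-definite m x m model covariance.
#' @return scalar cost (smaller is better).
#' @export
champagne_cost <- function(data, Sigma_y) {
  stopifnot(inherits(data, "snc_dataset"))
  Sigma_y <- as.matrix(Sigma_y)
  ld <- logdet_pd(sym(Sigma_y))
  W <- jitter_solve(sym(Sigma_y), data$y)
  ld + sum(data$y * W) / data$K
}

#' Source-variance update (evidence maximization step)
#'
#' The convex-bounding fixed-point update of the per-voxel source variances.
#' With \eqn{g_i = l_i^\top \Sigma_y^{-1} l_i} the default (`"sqrt"`) rule is
#' \deqn{v_i = \sqrt{ \tfrac1K \sum_k \bar x_k(i)^2 \;/\; g_i },}
#' the stationary point of the convex bound in the variance parametrization;
#' it is the rule that provably never increases [champagne_cost()].
#' `"as_printed"` applies the ratio without the square root (kept for fidelity
#' experiments; it does not inherit the monotonicity guarantee).
#'
#' Voxels whose updated variance falls below `prune_tol * max(v)` are clamped
#' to exactly 0 (hard automatic-relevance-determination pruning). A zero
#' lead-field column yields v_i = 0 with a warning.
#'
#' @param xbar n x K posterior means computed from the **same** `Sigma_y`.
#' @param lf [leadfield()].
#' @param Sigma_y the model covariance used to compute `xbar`.
#' @param variance_update `"sqrt"` (default) or `"as_printed"`.
#' @param prune_tol relative pruning threshold (default 1e-12).
#' @return nonnegative length-n vector of updated source variances.
#' @export
update_source_variances <- function(xbar, lf, Sigma_y,
                                    variance_update = c("sqrt", "as_printed"),
                                    prune_tol = 1e-12) {
  variance_update <- match.arg(variance_update)
  stopifnot(inherits(lf, "snc_leadfield"))
  xbar <- as.matrix(xbar)
  if (nrow(xbar) != lf$n) stop("xbar must have one row per voxel")
  SyinvL <- jitter_solve(sym(as.matrix(Sigma_y)), lf$gain)
  g <- colSums(lf$gain * SyinvL)                    # g_i = l_i' Sy^{-1} l_i
  zero_col <- colSums(lf$gain^2) == 0
  if (any(zero_col)) warning("lead-field has all-zero column(s); their variances set to 0")
  if (any(g[!zero_col] <= 0))
    stop("g_i <= 0 encountered for a nonzero lead-field column; Sigma_y not PD?")
  msq <- rowMeans(xbar^2)
  v <- numeric(lf$n)
  ok <- !zero_col
  v[ok] <- switch(variance_update,
                  sqrt = sqrt(msq[ok] / g[ok]),
                  as_printed = msq[ok] / g[ok])
  vmax <- max(v)
  if (vmax > 0) v[v < prune_tol * vmax] <- 0
  v
}
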