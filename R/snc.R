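#' Options for the structured-noise Champagne solver
#'
#' @param max_outer_iter maximum outer iterations (default 100).
#' @param outer_tol relative change of [champagne_cost()] that stops the outer
#'   loop (default 1e-6).
#' @param q noise factor count for the VBFA noise model, or `"auto"`
#'   (eigenvalue rule). Ignored unless `noise_kind = "structured"`.
#' @param noise_kind `"structured"` (default; low-rank + diagonal noise learned
#'   by VBFA), `"diagonal-learned"` (per-sensor variances only; identical to
#'   structured with q = 0), or `"fixed"` (noise covariance held at its
#'   initial value).
#' @param noise_update_every update the noise model every this many outer
#'   iterations (default 1).
#' @param noise_warmup number of initial outer iterations run with the fixed
#'   initial noise covariance before the first noise update (default 3). The
#'   warmup lets the source model claim the lead-field-spanned part of the
#'   data first; without it, at high SNR the factor model absorbs the
#'   (low-rank, inter-correlated) source activity into the noise estimate.
#' @param seed seed controlling the (only) stochastic ingredient, the VBFA
#'   initialization jitter.
#' @param variance_update `"sqrt"` (default) or `"as_printed"`; see
#'   [update_source_variances()].
#' @param noise_cov_mode `"fa_model"` (default) or `"as_printed"`; see
#'   [noise_covariance()].
#' @param initial_noise_scale the initial noise covariance is
#'   `initial_noise_scale * mean per-sensor power of y` times the identity
#'   (default 0.1); alternatively pass a full matrix via `initial_noise`.
#' @param initial_noise optional m x m initial noise covariance overriding the
#'   scaled identity.
#' @param vbfa_max_iter,vbfa_tol inner VBFA iteration controls.
#' @param prune_tol relative source-variance pruning threshold.
#' @return list of class `snc_options`.
#' @export
snc_options <- function(max_outer_iter = 100L, outer_tol = 1e-6, q = "auto",
                        noise_kind = c("structured", "diagonal-learned", "fixed"),
                        noise_update_every = 1L, noise_warmup = 3L, seed = 1L,
                        variance_update = c("sqrt", "as_printed"),
                        noise_cov_mode = c("fa_model", "as_printed"),
                        initial_noise_scale = 0.1, initial_noise = NULL,
                        vbfa_max_iter = 50L, vbfa_tol = 1e-6,
                        prune_tol = 1e-12) {
  noise_kind <- match.arg(noise_kind)
  variance_update <- match.arg(variance_update)
  noise_cov_mode <- match.arg(noise_cov_mode)
  if (max_outer_iter < 1L) stop("max_outer_iter must be >= 1")
  if (outer_tol <= 0 || vbfa_tol <= 0) stop("tolerances must be positive")
  if (noise_update_every < 1L) stop("noise_update_every must be >= 1")
  if (noise_warmup < 0L) stop("noise_warmup must be >= 0")
  structure(list(max_outer_iter = as.integer(max_outer_iter),
                 outer_tol = outer_tol, q = q, noise_kind = noise_kind,
                 noise_update_every = as.integer(noise_update_every),
                 noise_warmup = as.integer(noise_warmup),
                 seed = as.integer(seed), variance_update = variance_update,
                 noise_cov_mode = noise_cov_mode,
                 initial_noise_scale = initial_noise_scale,
                 initial_noise = initial_noise,
                 vbfa_max_iter = as.integer(vbfa_max_iter),
                 vbfa_tol = vbfa_tol, prune_tol = prune_tol),
            class = "snc_options")
}

#' Structured-noise Champagne source reconstruction
#'
#' The outer alternating algorithm. Per outer iteration l:
#' (1) posterior source means from the current noise covariance and source
#' variances; (2) evidence-maximization update of the source variances;
#' (3) re-estimation of the noise covariance by variational Bayesian factor
#' analysis of the residuals z_k = y_k - L xbar_k (low-rank + diagonal), or
#' per-sensor variances only (`noise_kind = "diagonal-learned"`), or no update
#' (`"fixed"`). The loop stops when the relative change of the marginal-
#' likelihood cost falls below `outer_tol`. Each iteration's VBFA warm-starts
#' from the previous iteration's state. The lead-field is column-normalized
#' internally if it is not already (source variances are then expressed in the
#' normalized convention).
#'
#' @param data [sensor_dataset()].
#' @param lf [leadfield()].
#' @param opts [snc_options()].
#' @return object of class `snc_result`: `source_variances`, `xbar` (n x K
#'   reconstructed time courses), `power_map` (per-voxel mean squared xbar),
#'   `noise` ([noise_model()]), `cost_trace`, `n_iter`, `best_iter`,
#'   `converged`, `diverged`, `residual_rms` (per-iteration), `vbfa` (VBFA
#'   state at the reported iterate, or NULL), `opts`. The reported state is
#'   the iterate with the lowest marginal-likelihood cost (with noise
#'   learning the outer cost is not guaranteed monotone, so the last iterate
#'   is not necessarily the best one).
#' @export
snc_fit <- function(data, lf, opts = snc_options()) {
  stopifnot(inherits(data, "snc_dataset"), inherits(lf, "snc_leadfield"),
            inherits(opts, "snc_options"))
  if (data$m != lf$m) stop("data and lead-field disagree on sensor count")
  if (!lf$normalized) lf <- normalize_leadfield(lf)
  Y <- data$y
  m <- data$m; K <- data$K; n <- lf$n
  L <- lf$gain

  noise <- if (!is.null(opts$initial_noise)) {
    noise_model(opts$initial_noise, kind = "fixed-diagonal")
  } else {
    scale0 <- opts$initial_noise_scale * mean(Y^2)
    if (scale0 <= 0) scale0 <- .Machine$double.eps   # all-zero data guard
    noise_model(diag(scale0, m), kind = "fixed-diagonal")
  }
  q_eff <- switch(opts$noise_kind,
                  structured = opts$q,
                  `diagonal-learned` = 0L,
                  fixed = NA)
  # Scale-aware source-variance init: total prior signal power sum(v) matches
  # 10% of the data power m*mean(Y^2). A scale-free init (v = 1) lets the
  # source model absorb the data whole on the first pass, collapsing the
  # residual -- and with it any learned noise estimate -- to zero.
  v <- rep(0.1 * m * mean(Y^2) / n, n)
  if (max(v) <= 0) v <- rep(.Machine$double.eps, n)
  best <- list(cost = Inf, v = v, noise = noise, vstate = NULL, iter = 0L)
  vstate <- NULL
  cost_trace <- numeric(0)
  residual_rms <- numeric(0)
  n_increase <- 0L
  converged <- FALSE
  diverged <- FALSE
  xbar <- matrix(0, n, K)

  for (l in seq_len(opts$max_outer_iter)) {
    Sigma_y <- compute_model_covariance(lf, v, noise)
    SyinvY <- jitter_solve(Sigma_y, Y)
    xbar <- v * (t(L) %*% SyinvY)
    v <- update_source_variances(xbar, lf, Sigma_y,
                                 variance_update = opts$variance_update,
                                 prune_tol = opts$prune_tol)
    z <- Y - L %*% xbar
    residual_rms <- c(residual_rms, sqrt(mean(z^2)))
    if (opts$noise_kind != "fixed" && l > opts$noise_warmup &&
        ((l - opts$noise_warmup) %% opts$noise_update_every == 0L)) {
      vstate <- vbfa_fit(z, q = q_eff, max_iter = opts$vbfa_max_iter,
                         tol = opts$vbfa_tol, seed = opts$seed, init = vstate)
      noise <- noise_covariance(vstate, mode = opts$noise_cov_mode)
    }
    cost <- champagne_cost(data, compute_model_covariance(lf, v, noise))
    cost_trace <- c(cost_trace, cost)
    if (cost < best$cost) {
      best <- list(cost = cost, v = v, noise = noise, vstate = vstate, iter = l)
    }
    if (l > 1L) {
      prev <- cost_trace[l - 1L]
      rel <- abs(cost - prev) / max(abs(prev), .Machine$double.eps)
      if (cost > prev + 1e-3 * abs(prev)) n_increase <- n_increase + 1L else n_increase <- 0L
      if (n_increase >= 5L) {
        diverged <- TRUE
        warning("champagne cost increased for 5 consecutive iterations; ",
                "aborting with diagnostic state at iteration ", l)
        break
      }
      if (rel < opts$outer_tol) {
        converged <- TRUE
        break
      }
    }
    if (max(v) == 0) { converged <- TRUE; break }    # all sources pruned
  }

  # Report the best-cost iterate: once the noise model couples in, the outer
  # cost can plateau and wobble, and the marginal likelihood -- the model's
  # own objective -- is the arbiter of which (v, Sigma_n) to keep.
  v <- best$v; noise <- best$noise; vstate <- best$vstate
  ps <- compute_posterior_sources(data, lf, v, noise)
  xbar <- ps$xbar
  structure(list(source_variances = v, xbar = xbar,
                 power_map = rowMeans(xbar^2), noise = noise,
                 cost_trace = cost_trace, n_iter = length(cost_trace),
                 best_iter = best$iter, converged = converged,
                 diverged = diverged, residual_rms = residual_rms,
                 vbfa = vstate, opts = opts),
            class = "snc_result")
}

#' @export
print.snc_result <- function(x, ...) {
  cat(sprintf(paste0("<snc_result> %d voxels, %d active (v > 0), %d iterations",
                     "%s; final cost %.6g\n"),
              length(x$source_variances), sum(x$source_variances > 0), x$n_iter,
              if (x$converged) " (converged)" else if (x$diverged) " (DIVERGED)" else "",
              if (x$n_iter > 0) x$cost_trace[x$n_iter] else NA_real_))
  invisible(x)
}

#' Per-voxel power of a reconstruction
#'
#' `power_map_i = (1/K) sum_k xbar_k(i)^2`, the quantity plotted in
#' voxel-power localization maps.
#'
#' @param result an `snc_result`, or any n x K matrix of time courses.
#' @return nonnegative length-n vector.
#' @export
reconstruct_power_map <- function(result) {
  xb <- if (inherits(result, "snc_result")) result$xbar else as.matrix(result)
  rowMeans(xb^2)
}
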