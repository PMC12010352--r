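#' Candidate detection and hit / false-positive rates
#'
#' Candidate voxels are those whose reconstructed power is (i) at least
#' `amp_frac` (default 1%) of the maximum activation AND (ii) within the
#' largest `top_frac` (default 10%) of all voxels (ties broken by voxel
#' index). A true source counts as a hit when at least one candidate lies
#' among its `n_near` (default 10) nearest voxels by Euclidean distance on the
#' voxel grid, the source voxel itself included (distance ties broken by voxel
#' index). `h_r` is hits over the number of true sources; `f_r` is the number
#' of candidates lying in no source's neighbourhood divided by the number of
#' candidates (so both rates live in [0, 1]).
#'
#' @param power_map nonnegative length-n vector.
#' @param true_voxels indices of the true source voxels.
#' @param voxel_coords n x 3 voxel positions.
#' @param amp_frac,top_frac,n_near detection rule parameters (defaults 0.01,
#'   0.10, 10).
#' @return list with `h_r`, `f_r`, `candidates` (indices), `hits` (logical per
#'   true source).
#' @export
compute_hits <- function(power_map, true_voxels, voxel_coords,
                         amp_frac = 0.01, top_frac = 0.10, n_near = 10L) {
  power_map <- as.numeric(power_map)
  n <- length(power_map)
  voxel_coords <- as.matrix(voxel_coords)
  if (nrow(voxel_coords) != n) stop("voxel_coords must have one row per voxel")
  if (length(true_voxels) == 0L) stop("true_voxels must be nonempty")
  if (any(power_map < 0)) stop("power map must be nonnegative")
  pmax_ <- max(power_map)
  if (pmax_ == 0) {
    warning("all-zero power map: no candidates")
    return(list(h_r = 0, f_r = 0, candidates = integer(0),
                hits = rep(FALSE, length(true_voxels))))
  }
  k_top <- ceiling(top_frac * n)
  ord <- order(-power_map, seq_len(n))               # ties by voxel index
  top_set <- ord[seq_len(k_top)]
  candidates <- sort(intersect(which(power_map >= amp_frac * pmax_), top_set))
  neighborhoods <- lapply(true_voxels, function(tv) {
    d <- sqrt(colSums((t(voxel_coords) - voxel_coords[tv, ])^2))
    order(d, seq_len(n))[seq_len(min(n_near, n))]    # includes tv (distance 0)
  })
  hits <- vapply(neighborhoods, function(nb) any(candidates %in% nb), logical(1))
  in_any <- if (length(candidates)) {
    all_nb <- unique(unlist(neighborhoods))
    candidates %in% all_nb
  } else logical(0)
  list(h_r = sum(hits) / length(true_voxels),
       f_r = sum(!in_any) / max(1L, length(candidates)),
       candidates = candidates, hits = hits)
}

#' A' detection summary
#'
#' Closed-form summary of the free-response operating point. The default
#' (`mode = "corrected"`) is `A' = (h_r - f_r)/2 + 1/2`, which is 1 at a
#' perfect (1, 0) operating point, 1/2 on the chance diagonal h = f, and 0 at
#' (0, 1). `mode = "as_printed"` applies `(h_r + f_r)/2 + 1/2`, which exceeds
#' 1 whenever h + f > 1 and rewards false positives; it is retained only for
#' fidelity comparisons.
#'
#' @param h_r,f_r rates in [0, 1].
#' @param mode `"corrected"` (default) or `"as_printed"`.
#' @return scalar.
#' @export
froc_aprime <- function(h_r, f_r, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (any(c(h_r, f_r) < 0) || any(c(h_r, f_r) > 1)) stop("rates must lie in [0, 1]")
  switch(mode,
         corrected = (h_r - f_r) / 2 + 0.5,
         as_printed = (h_r + f_r) / 2 + 0.5)
}

#' FROC curve and area
#'
#' Sweeps the relative activation threshold, recomputing the hit and
#' false-positive rates of [compute_hits()] at each threshold (the top-10%
#' cap is retained), and returns the trapezoidal area of hit rate over
#' false-positive rate with the curve anchored at (0, 0) and extended to
#' f = 1 at its maximal hit rate.
#'
#' @inheritParams compute_hits
#' @param thresholds relative thresholds swept (fractions of the map maximum).
#' @return list with `curve` (data.frame threshold, h_r, f_r) and `area`.
#' @export
froc_curve <- function(power_map, true_voxels, voxel_coords,
                       thresholds = seq(0, 1, by = 0.02),
                       top_frac = 0.10, n_near = 10L) {
  pts <- lapply(thresholds, function(th) {
    h <- suppressWarnings(
      compute_hits(power_map, true_voxels, voxel_coords,
                   amp_frac = th, top_frac = top_frac, n_near = n_near))
    c(threshold = th, h_r = h$h_r, f_r = h$f_r)
  })
  curve <- as.data.frame(do.call(rbind, pts))
  f <- c(0, sort(curve$f_r), 1)
  h <- c(0, curve$h_r[order(curve$f_r)], max(curve$h_r))
  # enforce a nondecreasing staircase before integrating
  h <- cummax(h)
  area <- sum(diff(f) * (head(h, -1) + tail(h, -1)) / 2)
  list(curve = curve, area = area)
}

#' Mean absolute time-course correlation over hits
#'
#' For each hit source, the Pearson correlation between its true time course
#' and the estimated time course at the best-matching candidate voxel (largest
#' absolute correlation among the candidates inside its nearest-neighbour
#' set). The absolute value is taken: source orientation leaves the sign
#' indeterminate. Returns 0 when there are no hits; constant time courses
#' correlate as 0 with a warning.
#'
#' @param xbar n x K estimated time courses.
#' @param truth list with `source_voxels`, `source_timecourses` (s x K).
#' @param hit_info output of [compute_hits()] for the same reconstruction.
#' @param voxel_coords n x 3 voxel positions.
#' @param n_near neighbourhood size (default 10).
#' @return scalar `r_bar` in [0, 1].
#' @export
timecourse_correlation <- function(xbar, truth, hit_info, voxel_coords,
                                   n_near = 10L) {
  if (!any(hit_info$hits)) return(0)
  xbar <- as.matrix(xbar)
  voxel_coords <- as.matrix(voxel_coords)
  n <- nrow(xbar)
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) {
      warning("constant time course; correlation defined as 0")
      return(0)
    }
    cor(a, b)
  }
  rs <- vapply(which(hit_info$hits), function(si) {
    tv <- truth$source_voxels[si]
    d <- sqrt(colSums((t(voxel_coords) - voxel_coords[tv, ])^2))
    nb <- order(d, seq_len(n))[seq_len(min(n_near, n))]
    cand <- intersect(hit_info$candidates, nb)
    max(vapply(cand, function(ci) {
      abs(safe_cor(truth$source_timecourses[si, ], xbar[ci, ]))
    }, numeric(1)))
  }, numeric(1))
  mean(rs)
}

#' Aggregate performance
#'
#' `AP = (A' + h_r * R_bar) / 2`, combining localization (A') and time-course
#' fidelity (correlation over hits); bounded in [0, 1].
#'
#' @param a_prime,h_r,r_bar component scores, each in [0, 1].
#' @return scalar in [0, 1].
#' @export
aggregate_performance <- function(a_prime, h_r, r_bar) {
  vals <- c(a_prime, h_r, r_bar)
  if (any(vals < 0) || any(vals > 1)) stop("all inputs must lie in [0, 1]")
  (a_prime + h_r * r_bar) / 2
}

#' Affine-invariant geodesic distance between SPD matrices
#'
#' `d(S1, S2) = || log(S1^{-1/2} S2 S1^{-1/2}) ||_F` computed by
#' eigendecomposition; the natural Riemannian distance on the SPD cone,
#' symmetric and invariant under congruence `S -> M S M'`. Near-singular
#' inputs are regularized by `1e-10 * trace/m` on the diagonal.
#'
#' @param S1,S2 symmetric positive (semi-)definite matrices.
#' @return nonnegative scalar.
#' @export
geodesic_distance <- function(S1, S2) {
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  m <- nrow(S1)
  if (!all(dim(S1) == c(m, m)) || !all(dim(S2) == c(m, m)))
    stop("S1 and S2 must be square matrices of equal size")
  chk <- function(S, nm) {
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      stop(nm, " is not symmetric")
    sym(S)
  }
  S1 <- chk(S1, "S1"); S2 <- chk(S2, "S2")
  reg <- function(S) {
    eps <- 1e-10 * sum(diag(S)) / m
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= eps) S + diag(max(eps, .Machine$double.eps), m) else S
  }
  S1 <- reg(S1); S2 <- reg(S2)
  e1 <- eigen(S1, symmetric = TRUE)
  isq <- e1$vectors %*% (t(e1$vectors) / sqrt(pmax(e1$values, .Machine$double.eps)))
  Mmat <- sym(isq %*% S2 %*% isq)
  ev <- eigen(Mmat, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, .Machine$double.eps))^2))
}

#' Score one reconstruction against simulation truth
#'
#' Applies the detection rules, the A' closed form, the time-course
#' correlation over hits and the aggregate performance, plus (when a noise
#' estimate and true noise covariance are available) the SPD geodesic distance
#' between them.
#'
#' @param power_map length-n reconstructed power map.
#' @param xbar n x K reconstructed time courses.
#' @param truth the `truth` element of a [simulate_scene()] scene.
#' @param voxel_coords n x 3 voxel positions.
#' @param noise_cov optional estimated noise covariance (m x m).
#' @param aprime_mode passed to [froc_aprime()].
#' @return list of class `snc_metrics`: `h_r`, `f_r`, `a_prime`, `r_bar`,
#'   `ap`, `geodesic` (or NA), `hits`, `n_candidates`.
#' @export
evaluate_reconstruction <- function(power_map, xbar, truth, voxel_coords,
                                    noise_cov = NULL,
                                    aprime_mode = "corrected") {
  hi <- compute_hits(power_map, truth$source_voxels, voxel_coords)
  a_prime <- froc_aprime(hi$h_r, hi$f_r, mode = aprime_mode)
  r_bar <- timecourse_correlation(xbar, truth, hi, voxel_coords)
  geo <- if (!is.null(noise_cov) && !is.null(truth$true_noise_covariance)) {
    geodesic_distance(truth$true_noise_covariance, noise_cov)
  } else NA_real_
  structure(list(h_r = hi$h_r, f_r = hi$f_r, a_prime = a_prime, r_bar = r_bar,
                 ap = (a_prime + hi$h_r * r_bar) / 2,
                 geodesic = geo, hits = hi$hits,
                 n_candidates = length(hi$candidates)),
            class = "snc_metrics")
}

#' @export
print.snc_metrics <- function(x, ...) {
  cat(sprintf("<snc_metrics> h_r %.3f  f_r %.3f  A' %.3f  R_bar %.3f  AP %.3f  geodesic %s\n",
              x$h_r, x$f_r, x$a_prime, x$r_bar, x$ap,
              if (is.na(x$geodesic)) "-" else sprintf("%.3f", x$geodesic)))
  invisible(x)
}
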