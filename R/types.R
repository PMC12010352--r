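#' Lead-field (forward gain) matrix
#'
#' Bundles the m x n gain matrix mapping unit-amplitude current sources at n
#' brain voxels to m sensors with the voxel grid coordinates. Columns are the
#' per-voxel sensor topographies (fixed orientation, one column per voxel).
#'
#' @param gain numeric m x n matrix; column i is the sensor response to a unit
#'   source at voxel i.
#' @param voxel_coords numeric n x 3 matrix of voxel positions (mm).
#' @param normalized logical; `TRUE` asserts every column has unit Euclidean
#'   norm (checked to 1e-12).
#' @return An object of class `snc_leadfield` with elements `gain`,
#'   `voxel_coords`, `normalized`, `m`, `n`.
#' @seealso [normalize_leadfield()], [make_leadfield()]
#' @export
leadfield <- function(gain, voxel_coords, normalized = FALSE) {
  gain <- as.matrix(gain)
  voxel_coords <- as.matrix(voxel_coords)
  if (nrow(gain) < 1L || ncol(gain) < 1L) stop("gain must be at least 1 x 1")
  stopifnot_finite(gain, "gain")
  if (nrow(voxel_coords) != ncol(gain) || ncol(voxel_coords) != 3L)
    stop("voxel_coords must be n x 3 with n = ncol(gain)")
  if (normalized) {
    nrm <- sqrt(colSums(gain^2))
    if (any(abs(nrm - 1) > 1e-12))
      stop("normalized = TRUE but some column norms deviate from 1 by more than 1e-12")
  }
  structure(list(gain = gain, voxel_coords = voxel_coords,
                 normalized = isTRUE(normalized),
                 m = nrow(gain), n = ncol(gain)),
            class = "snc_leadfield")
}

#' Normalize lead-field columns to unit norm
#'
#' @param lf an [leadfield()] object.
#' @return The lead-field with every column scaled to Euclidean norm 1.
#'   All-zero columns are an error: a zero topography carries no information
#'   and cannot be normalized.
#' @export
normalize_leadfield <- function(lf) {
  stopifnot(inherits(lf, "snc_leadfield"))
  nrm <- sqrt(colSums(lf$gain^2))
  if (any(nrm == 0)) stop("cannot normalize: lead-field has all-zero column(s)")
  leadfield(sweep(lf$gain, 2L, nrm, "/"), lf$voxel_coords, normalized = TRUE)
}

#' @export
print.snc_leadfield <- function(x, ...) {
  cat(sprintf("<snc_leadfield> %d sensors x %d voxels%s\n", x$m, x$n,
              if (x$normalized) ", unit-norm columns" else ""))
  invisible(x)
}

#' Sensor measurement container
#'
#' The solver's observable: an m x K matrix of sensor measurements (one column
#' per time sample) plus the sampling rate.
#'
#' @param y numeric m x K matrix of sensor data (e.g. fT).
#' @param fs sampling rate in Hz.
#' @return An object of class `snc_dataset` with `y`, `fs`, `times`
#'   (K sample instants starting at 0, spacing 1/fs), `m`, `K`.
#' @export
sensor_dataset <- function(y, fs) {
  y <- as.matrix(y)
  if (ncol(y) < 1L) stop("need at least one time sample (K >= 1)")
  stopifnot_finite(y, "y")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  structure(list(y = y, fs = fs, times = (seq_len(ncol(y)) - 1L) / fs,
                 m = nrow(y), K = ncol(y)),
            class = "snc_dataset")
}

#' @export
print.snc_dataset <- function(x, ...) {
  cat(sprintf("<snc_dataset> %d sensors x %d samples @ %g Hz (%.3f s)\n",
              x$m, x$K, x$fs, x$K / x$fs))
  invisible(x)
}

#' Sensor-noise model
#'
#' Stores the noise **covariance** Sigma_n (the precision is derived on
#' demand with a jitter-guarded inverse). The covariance convention is the
#' only one that keeps the model covariance, posterior mean and the factor
#' analysis noise estimate mutually consistent.
#'
#' @param covariance symmetric positive semi-definite m x m matrix.
#' @param kind one of `"fixed-diagonal"`, `"learned-diagonal"`, `"structured"`.
#' @return An object of class `snc_noise_model` with `covariance`, `kind`, `m`.
#' @export
noise_model <- function(covariance,
                        kind = c("fixed-diagonal", "learned-diagonal", "structured")) {
  kind <- match.arg(kind)
  covariance <- as.matrix(covariance)
  m <- nrow(covariance)
  if (ncol(covariance) != m) stop("covariance must be square")
  stopifnot_finite(covariance, "covariance")
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance))))
    stop("covariance must be symmetric")
  covariance <- sym(covariance)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(sum(diag(covariance)), .Machine$double.eps))
    stop("covariance has a substantially negative eigenvalue; not PSD")
  structure(list(covariance = covariance, kind = kind, m = m),
            class = "snc_noise_model")
}

#' Noise precision matrix
#'
#' Inverse of the stored noise covariance, computed with escalating diagonal
#' jitter when the covariance is near-singular.
#'
#' @param noise an [noise_model()] object.
#' @return m x m precision matrix.
#' @export
noise_precision <- function(noise) {
  stopifnot(inherits(noise, "snc_noise_model"))
  sym(jitter_solve(noise$covariance))
}

#' @export
print.snc_noise_model <- function(x, ...) {
  cat(sprintf("<snc_noise_model> %d x %d, kind = %s, trace = %.4g\n",
              x$m, x$m, x$kind, sum(diag(x$covariance))))
  invisible(x)
}
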