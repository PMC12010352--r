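#' Synthetic lead-field generator
#'
#' Builds a unit-column-norm gain matrix over a synthetic 3-D voxel grid.
#' Geometry `"random-smooth"` (default) draws each column as a spatially
#' smooth random field: sensor loadings are mixed through Gaussian radial
#' basis functions of the voxel coordinates, so neighbouring voxels have
#' similar topographies, as in a physical forward model. Geometry
#' `"gaussian"` draws i.i.d. Gaussian columns (a stress-test geometry with no
#' spatial structure). Both are deterministic functions of the seed.
#'
#' @param m number of sensors (>= 2).
#' @param n number of voxels (n >= m recommended).
#' @param geometry `"random-smooth"` or `"gaussian"`.
#' @param seed RNG seed.
#' @param spacing_mm voxel grid spacing in mm (default 5, a typical MEG
#'   source-grid resolution).
#' @return an [leadfield()] with `normalized = TRUE` and grid coordinates.
#' @export
make_leadfield <- function(m, n, geometry = c("random-smooth", "gaussian"),
                           seed = 1L, spacing_mm = 5) {
  geometry <- match.arg(geometry)
  if (m < 2L) stop("need at least m = 2 sensors")
  # near-cubic integer grid covering n voxels
  side <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(ceiling(n / side^2))))
  coords <- grid[seq_len(n), , drop = FALSE] * spacing_mm
  storage.mode(coords) <- "double"
  gain <- with_local_seed(seed, {
    if (geometry == "gaussian") {
      matrix(rnorm(m * n), m, n)
    } else {
      p <- min(n, max(2L * m, 40L))                  # RBF basis size
      centers <- coords[sample.int(n, min(p, n)), , drop = FALSE]
      width <- 1.5 * spacing_mm                      # smoothness length scale:
      # topographies decorrelate over a few voxel spacings, as in a physical
      # forward model (neighbours similar, distant voxels distinguishable)
      d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
        2 * coords %*% t(centers)
      B <- exp(-pmax(d2, 0) / (2 * width^2))         # n x p smooth basis
      S <- matrix(rnorm(m * nrow(centers)), m)       # random sensor loadings
      S %*% t(B) + 0.05 * matrix(rnorm(m * n), m, n)
    }
  })
  nrm <- sqrt(colSums(gain^2))
  leadfield(sweep(gain, 2L, nrm, "/"), coords, normalized = TRUE)
}

#' Damped-sinusoid source time courses with controlled correlation
#'
#' Each source is a damped sinusoid `exp(-t/tau) * sin(2*pi*f*t + phi)` with
#' frequency drawn uniformly from `freq_range`. Pairwise correlation is
#' imposed by mixing a shared latent damped sinusoid g with independent ones:
#' `s_i = sqrt(corr) * g + sqrt(1 - corr) * h_i`, after normalizing each
#' component to unit sample norm, which gives population correlation `corr`
#' between any two sources. `corr = 1` returns identical time courses.
#'
#' @param n_sources number of sources.
#' @param K samples (default 480).
#' @param fs sampling rate in Hz (default 1200).
#' @param freq_range length-2 frequency range in Hz (default c(1, 75)).
#' @param corr pairwise source correlation in [0, 1].
#' @param seed RNG seed.
#' @param tau damping constant in seconds (default 0.25: visible decay within
#'   the default 0.4 s window).
#' @return list with `timecourses` (n_sources x K), `freqs`, `phases`, `tau`,
#'   `times`.
#' @export
simulate_sources <- function(n_sources, K = 480L, fs = 1200, freq_range = c(1, 75),
                             corr = 0.99, seed = 1L, tau = 0.25) {
  if (corr < 0 || corr > 1) stop("corr must lie in [0, 1]")
  if (n_sources < 1L) stop("need at least one source")
  tt <- (seq_len(K) - 1L) / fs
  out <- with_local_seed(seed, {
    damped <- function() {
      f <- runif(1, freq_range[1], freq_range[2])
      phi <- runif(1, 0, 2 * pi)
      s <- exp(-tt / tau) * sin(2 * pi * f * tt + phi)
      list(s = s / max(sqrt(sum(s^2)), .Machine$double.eps), f = f, phi = phi)
    }
    g <- damped()
    hs <- replicate(n_sources, damped(), simplify = FALSE)
    S <- t(vapply(hs, function(h) {
      sqrt(corr) * g$s + sqrt(1 - corr) * h$s
    }, numeric(K)))
    list(S = S, freqs = c(shared = g$f, vapply(hs, `[[`, numeric(1), "f")),
         phases = c(shared = g$phi, vapply(hs, `[[`, numeric(1), "phi")))
  })
  list(timecourses = out$S, freqs = out$freqs, phases = out$phases,
       tau = tau, times = tt)
}

#' Low-rank structured sensor noise
#'
#' Draws `noise = B U + E` with a seeded Gaussian m x q mixing matrix B,
#' standard-normal factors U (q x K) and independent diagonal Gaussian sensor
#' noise E with variance `diag_scale`. The population covariance is
#' `B B' + diag_scale * I` (rank-q structure plus a full-rank diagonal floor).
#'
#' @param m sensors.
#' @param K samples.
#' @param q number of noise factors (0 <= q <= m); q = 0 gives white noise.
#' @param diag_scale variance of the diagonal (sensor) noise component
#'   (default 1).
#' @param seed RNG seed.
#' @return list with `noise` (m x K), `covariance` (m x m population
#'   covariance), `B`.
#' @export
simulate_structured_noise <- function(m, K, q, diag_scale = 1, seed = 1L) {
  if (q < 0 || q > m) stop("q must lie in [0, m]")
  if (diag_scale <= 0) stop("diag_scale must be positive")
  out <- with_local_seed(seed, {
    B <- if (q > 0) matrix(rnorm(m * q), m, q) else matrix(0, m, 0L)
    U <- if (q > 0) matrix(rnorm(q * K), q, K) else matrix(0, 0L, K)
    E <- matrix(rnorm(m * K, sd = sqrt(diag_scale)), m, K)
    list(noise = (if (q > 0) B %*% U else matrix(0, m, K)) + E, B = B)
  })
  list(noise = out$noise, covariance = sym(out$B %*% t(out$B)) + diag(diag_scale, m),
       B = out$B)
}

#' Mix clean signal and noise at a target SNR
#'
#' Scales the noise by c so that the sensor-level SNR, defined as the
#' Frobenius-norm power ratio in decibels
#' `20 * log10(||clean||_F / ||c * noise||_F)`, equals `snr_db` exactly.
#'
#' @param clean m x K noiseless sensor signal (L x).
#' @param noise m x K noise realization (not identically zero).
#' @param snr_db target SNR in dB.
#' @return list with `y = clean + c * noise` and `noise_scale = c`.
#' @export
mix_at_snr <- function(clean, noise, snr_db) {
  clean <- as.matrix(clean); noise <- as.matrix(noise)
  if (!all(dim(clean) == dim(noise))) stop("clean and noise dimensions differ")
  nc <- sqrt(sum(clean^2)); nn <- sqrt(sum(noise^2))
  if (nc == 0) stop("clean signal is identically zero; SNR undefined")
  if (nn == 0) stop("noise is identically zero; cannot scale to a finite SNR")
  c0 <- nc / (nn * 10^(snr_db / 20))
  list(y = clean + c0 * noise, noise_scale = c0)
}

#' Full simulation scene with ground truth
#'
#' Composes the generators into the standard protocol: a unit-norm lead-field
#' over a synthetic grid, `n_sources` damped-sinusoid sources with pairwise
#' correlation `corr` placed at seeded distinct voxels, low-rank structured
#' noise with `q_noise` factors, mixed at `snr_db`. Defaults follow the
#' reference MEG protocol: 271 sensors, 480 samples at 1200 Hz, five sources
#' with correlation 0.99 at 3 dB SNR, 40 noise factors. Tests use a scaled
#' down scene (m = 40, n = 200, q = 5) for speed.
#'
#' @param m,n,K,fs,geometry,spacing_mm lead-field / sampling parameters.
#' @param n_sources,corr,freq_range,tau source parameters.
#' @param q_noise,noise_diag_scale structured-noise parameters.
#' @param snr_db target sensor SNR in dB.
#' @param seed single seed controlling the whole scene.
#' @return list of class `snc_scene` with `data` ([sensor_dataset()]),
#'   `leadfield`, and `truth` (source voxel indices, time courses, clean and
#'   noise sensor signals, true noise covariance incl. the SNR scaling,
#'   `snr_db`, `noise_scale`, `seed`).
#' @export
simulate_scene <- function(m = 271L, n = 8196L, K = 480L, fs = 1200,
                           n_sources = 5L, corr = 0.99, freq_range = c(1, 75),
                           tau = 0.25, q_noise = 40L, noise_diag_scale = 1,
                           snr_db = 3, seed = 1L,
                           geometry = "random-smooth", spacing_mm = 5) {
  lf <- make_leadfield(m, n, geometry = geometry, seed = seed, spacing_mm = spacing_mm)
  src <- simulate_sources(n_sources, K = K, fs = fs, freq_range = freq_range,
                          corr = corr, seed = seed + 1L, tau = tau)
  voxels <- with_local_seed(seed + 2L, sample.int(n, n_sources))
  clean <- lf$gain[, voxels, drop = FALSE] %*% src$timecourses
  noi <- simulate_structured_noise(m, K, q_noise, diag_scale = noise_diag_scale,
                                   seed = seed + 3L)
  mx <- mix_at_snr(clean, noi$noise, snr_db)
  truth <- list(source_voxels = voxels, source_timecourses = src$timecourses,
                clean_sensor = clean, noise_sensor = mx$noise_scale * noi$noise,
                true_noise_covariance = mx$noise_scale^2 * noi$covariance,
                snr_db = snr_db, noise_scale = mx$noise_scale, seed = seed,
                q_noise = q_noise, corr = corr)
  structure(list(data = sensor_dataset(mx$y, fs), leadfield = lf, truth = truth),
            class = "snc_scene")
}

#' @export
print.snc_scene <- function(x, ...) {
  cat(sprintf(paste0("<snc_scene> %d sensors x %d samples, %d voxels; %d sources ",
                     "(corr %.2f), %d noise factors, SNR %+g dB, seed %d\n"),
              x$data$m, x$data$K, x$leadfield$n, length(x$truth$source_voxels),
              x$truth$corr, x$truth$q_noise, x$truth$snr_db, x$truth$seed))
  invisible(x)
}
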