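# Independent reference implementations and fixture builders used across the
# suite. Everything here is deliberately naive (loops, closed forms, direct
# densities) so it shares no code path with the package internals it checks.

rand_spd <- function(m, scale = 1) {
  A <- matrix(rnorm(m * m), m)
  crossprod(A) / m + diag(scale, m)
}

rand_leadfield <- function(m, n) {
  G <- matrix(rnorm(m * n), m, n)
  G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
  leadfield(G, cbind(seq_len(n), 0, 0), normalized = TRUE)
}

# Joint Gaussian log-density of the columns of Y under N(0, Sigma), computed
# by whitening with the Cholesky factor and summing univariate log-densities.
gauss_logdens <- function(Y, Sigma) {
  R <- chol(Sigma)
  W <- forwardsolve(t(R), Y)
  sum(dnorm(W, log = TRUE)) - ncol(Y) * sum(log(diag(R)))
}

# Brute-force detection rules: double loops, no vectorized tricks.
naive_hits <- function(power, true_voxels, coords, amp_frac = 0.01,
                       top_frac = 0.10, n_near = 10) {
  n <- length(power)
  if (max(power) == 0) return(list(h_r = 0, f_r = 0))
  k_top <- ceiling(top_frac * n)
  ord <- order(-power, seq_len(n))
  in_top <- seq_len(n) %in% ord[1:k_top]
  cand <- c()
  for (i in seq_len(n))
    if (power[i] >= amp_frac * max(power) && in_top[i]) cand <- c(cand, i)
  near <- function(tv) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((coords[j, ] - coords[tv, ])^2))
    order(d, seq_len(n))[1:min(n_near, n)]
  }
  hits <- 0
  covered <- rep(FALSE, length(cand))
  for (tv in true_voxels) {
    nb <- near(tv)
    got <- FALSE
    for (ci in seq_along(cand)) {
      if (cand[ci] %in% nb) { got <- TRUE; covered[ci] <- TRUE }
    }
    if (got) hits <- hits + 1
  }
  list(h_r = hits / length(true_voxels),
       f_r = if (length(cand) == 0) 0 else sum(!covered) / length(cand),
       candidates = cand)
}

naive_rbar <- function(xbar, truth, coords, n_near = 10,
                       amp_frac = 0.01, top_frac = 0.10) {
  power <- rowMeans(xbar^2)
  hi <- naive_hits(power, truth$source_voxels, coords, amp_frac, top_frac, n_near)
  n <- nrow(xbar)
  rs <- c()
  for (si in seq_along(truth$source_voxels)) {
    tv <- truth$source_voxels[si]
    d <- sqrt(colSums((t(coords) - coords[tv, ])^2))
    nb <- order(d, seq_len(n))[1:min(n_near, n)]
    cand_nb <- intersect(hi$candidates, nb)
    if (length(cand_nb) == 0) next
    best <- 0
    for (ci in cand_nb)
      best <- max(best, abs(cor(truth$source_timecourses[si, ], xbar[ci, ])))
    rs <- c(rs, best)
  }
  if (length(rs) == 0) 0 else mean(rs)
}

# A small fast scene for solver tests.
tiny_scene <- function(seed = 1, snr_db = 3, m = 24, n = 80, K = 120,
                       n_sources = 3, q_noise = 3, corr = 0.9) {
  simulate_scene(m = m, n = n, K = K, n_sources = n_sources, corr = corr,
                 q_noise = q_noise, snr_db = snr_db, seed = seed)
}
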