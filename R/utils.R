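#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif cor sd median optimize quantile
#' @importFrom utils modifyList write.csv read.csv head tail
NULL

# Symmetrize a square matrix: (S + S')/2.
sym <- function(S) (S + t(S)) / 2

# log-determinant of a symmetric positive-definite matrix via Cholesky.
logdet_pd <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) stop("matrix is not positive definite (Cholesky failed)")
  2 * sum(log(diag(R)))
}

# Solve S X = B for symmetric S with an escalating diagonal jitter:
# start at 1e-10 * trace(S)/m, escalate x10 up to 1e-6 * trace(S)/m, then fail.
jitter_solve <- function(S, B = diag(nrow(S)), jitter0 = 1e-10, jitter_max = 1e-6) {
  m <- nrow(S)
  scale <- sum(diag(S)) / m
  if (!is.finite(scale) || scale <= 0) scale <- 1
  eps <- 0
  repeat {
    out <- tryCatch({
      R <- chol(S + diag(eps, m))
      backsolve(R, forwardsolve(t(R), B))
    }, error = function(e) NULL)
    if (!is.null(out)) return(out)
    eps <- if (eps == 0) jitter0 * scale else eps * 10
    if (eps > jitter_max * scale) {
      stop("matrix singular beyond jitter budget (condition too poor); ",
           "trace/m = ", format(scale))
    }
  }
}

# Cholesky factor with the same jitter policy; returns upper-triangular R.
jitter_chol <- function(S, jitter0 = 1e-10, jitter_max = 1e-6) {
  m <- nrow(S)
  scale <- sum(diag(S)) / m
  if (!is.finite(scale) || scale <= 0) scale <- 1
  eps <- 0
  repeat {
    R <- tryCatch(chol(S + diag(eps, m)), error = function(e) NULL)
    if (!is.null(R)) return(R)
    eps <- if (eps == 0) jitter0 * scale else eps * 10
    if (eps > jitter_max * scale) stop("matrix singular beyond jitter budget")
  }
}

# Run expr with a local RNG seed, restoring the caller's RNG state afterwards,
# so every generator is a pure function of its arguments.
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite entries")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
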