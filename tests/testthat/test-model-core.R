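test_that("model covariance: closed-form cases and input validation", {
  m <- 4
  lf <- leadfield(diag(m), cbind(1:m, 0, 0))
  nm <- noise_model(diag(m))
  expect_equal(compute_model_covariance(lf, rep(0, m), nm), diag(m))
  expect_equal(compute_model_covariance(lf, rep(1, m), nm), 2 * diag(m))
  expect_error(compute_model_covariance(lf, rep(1, m + 1), nm), "length")
  expect_error(compute_model_covariance(lf, c(1, NA, 1, 1), nm), "non-finite")
  expect_error(compute_model_covariance(lf, c(-1, 1, 1, 1), nm), "nonnegative")
})

test_that("model covariance matches the Monte-Carlo sample covariance", {
  set.seed(42)
  m <- 6; n <- 10; K <- 200000
  lf <- rand_leadfield(m, n)
  v <- runif(n, 0.2, 2)
  Sn <- rand_spd(m, 0.5)
  nm <- noise_model(Sn)
  Sy <- compute_model_covariance(lf, v, nm)
  X <- sqrt(v) * matrix(rnorm(n * K), n, K)
  Z <- t(chol(Sn)) %*% matrix(rnorm(m * K), m, K)
  Y <- lf$gain %*% X + Z
  S_hat <- Y %*% t(Y) / K
  expect_lt(norm(S_hat - Sy, "F") / norm(Sy, "F"), 0.02)
})

test_that("posterior mean: trivial cases and the scalar Wiener filter", {
  m <- 3
  lf <- rand_leadfield(m, 5)
  nm <- noise_model(diag(m))
  d <- sensor_dataset(matrix(rnorm(m * 4), m), fs = 100)
  expect_equal(compute_posterior_sources(d, lf, rep(0, 5), nm)$xbar,
               matrix(0, 5, 4))
  # m = n = 1, L = 1, noise var 1, v = 1, y = 2 -> xbar = 2 * 1 / (1 + 1) = 1
  lf1 <- leadfield(matrix(1), cbind(1, 0, 0))
  d1 <- sensor_dataset(matrix(2), fs = 1)
  expect_equal(as.numeric(compute_posterior_sources(d1, lf1, 1, noise_model(matrix(1)))$xbar), 1)
})

test_that("posterior mean agrees with the matrix-inversion-lemma form", {
  set.seed(7)
  for (rep in 1:20) {
    m <- 5; n <- 8; K <- 3
    lf <- rand_leadfield(m, n)
    v <- runif(n, 0.1, 2)
    Sn <- rand_spd(m)
    nm <- noise_model(Sn)
    d <- sensor_dataset(matrix(rnorm(m * K), m, K), fs = 100)
    ps <- compute_posterior_sources(d, lf, v, nm, return_precision = TRUE)
    # oracle: xbar = Gamma^{-1} L' Lambda y with Gamma = diag(1/v) + L' Lambda L
    Lam <- solve(Sn)
    Gam <- diag(1 / v) + t(lf$gain) %*% Lam %*% lf$gain
    xo <- solve(Gam, t(lf$gain) %*% Lam %*% d$y)
    expect_lt(max(abs(ps$xbar - xo)), 1e-9)
    expect_lt(max(abs(ps$posterior_precision - Gam)), 1e-6 * max(abs(Gam)))
  }
})

test_that("champagne cost: closed forms and Gaussian log-density oracle", {
  m <- 3; K <- 5
  Sy <- rand_spd(m)
  d0 <- sensor_dataset(matrix(0, m, K), fs = 10)
  expect_equal(champagne_cost(d0, Sy), determinant(Sy, logarithm = TRUE)$modulus[[1]])
  d1 <- sensor_dataset(matrix(2), fs = 1)
  expect_equal(champagne_cost(d1, matrix(1)), 4)
  set.seed(11)
  for (rep in 1:10) {
    m <- sample(2:6, 1); K <- sample(2:10, 1)
    Sy <- rand_spd(m)
    Y <- matrix(rnorm(m * K), m, K)
    d <- sensor_dataset(Y, fs = 100)
    oracle <- -(2 / K) * gauss_logdens(Y, Sy) - m * log(2 * pi)
    expect_lt(abs(champagne_cost(d, Sy) - oracle), 1e-9)
  }
  expect_error(champagne_cost(d1, matrix(-1)), "positive definite")
})

test_that("variance update: zero rows, zero columns, and the 1-D bound minimizer", {
  m <- 3
  lf <- rand_leadfield(m, 4)
  Sy <- rand_spd(m)
  xb <- matrix(rnorm(4 * 6), 4, 6)
  xb[2, ] <- 0
  v <- update_source_variances(xb, lf, Sy)
  expect_equal(v[2], 0)
  expect_true(all(v >= 0))

  G <- lf$gain; G[, 3] <- 0
  lfz <- leadfield(G, lf$voxel_coords)
  expect_warning(vz <- update_source_variances(xb, lfz, Sy), "all-zero column")
  expect_equal(vz[3], 0)

  # scalar case: the update must be the minimizer over v >= 0 of the bound
  # F(v) = mean(xbar^2)/v + g*v (+ const), found by grid search + refinement
  xb1 <- matrix(c(1.3, -0.4, 2.2), 1)
  Sy1 <- matrix(2.5)
  lf1 <- leadfield(matrix(1), cbind(1, 0, 0))
  v1 <- update_source_variances(xb1, lf1, Sy1)
  g <- 1 / 2.5
  f <- function(v) mean(xb1^2) / v + g * v
  grid <- seq(1e-4, 50, length.out = 20000)
  v_grid <- grid[which.min(sapply(grid, f))]
  v_opt <- optimize(f, c(max(v_grid - 0.1, 1e-6), v_grid + 0.1), tol = 1e-12)$minimum
  expect_lt(abs(v1 - v_opt) / v_opt, 1e-6)
})

test_that("full variance sweeps never increase the champagne cost", {
  set.seed(21)
  for (rep in 1:20) {
    m <- sample(2:6, 1); n <- sample(3:10, 1); K <- sample(2:20, 1)
    lf <- rand_leadfield(m, n)
    nm <- noise_model(rand_spd(m, 0.3))
    d <- sensor_dataset(matrix(rnorm(m * K), m, K), fs = 100)
    v <- runif(n, 0.1, 1)
    cost <- champagne_cost(d, compute_model_covariance(lf, v, nm))
    for (sweep in 1:5) {
      Sy <- compute_model_covariance(lf, v, nm)
      xb <- compute_posterior_sources(d, lf, v, nm)$xbar
      v <- update_source_variances(xb, lf, Sy)
      newcost <- champagne_cost(d, compute_model_covariance(lf, v, nm))
      expect_lte(newcost, cost + 1e-8 * abs(cost))
      cost <- newcost
    }
  }
})

test_that("a single active source is recovered in the near-noiseless limit", {
  set.seed(5)
  lf <- make_leadfield(40, 200, "gaussian", seed = 5)
  s <- sin(2 * pi * 7 * (0:99) / 250)
  y <- lf$gain[, 7, drop = FALSE] %*% t(as.matrix(s))
  d <- sensor_dataset(y, fs = 250)
  nm <- noise_model(diag(1e-8, 40))
  v <- rep(mean(y^2), 200)
  for (it in 1:60) {
    Sy <- compute_model_covariance(lf, v, nm)
    xb <- compute_posterior_sources(d, lf, v, nm)$xbar
    v <- update_source_variances(xb, lf, Sy)
  }
  expect_equal(which.max(v), 7L)
  expect_gt(v[7] / sum(v), 0.99)
})
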