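make_state <- function(A, Omega_inv, alpha, Psi, z) {
  st <- sncmeg:::new_vbfa_state(A, Omega_inv, alpha, Psi, z %*% t(z), ncol(z))
  st
}

test_that("e-step closed forms with A = 0", {
  m <- 4; q <- 2; K <- 6
  set.seed(1)
  z <- matrix(rnorm(m * K), m, K)
  Psi <- diag(c(2, 4))
  st <- make_state(matrix(0, m, q), rep(1, m), rep(1, q), Psi, z)
  st <- vbfa_e_step(z, st)
  expect_equal(st$ubar, matrix(0, q, K))
  expect_equal(st$Sigma_u, m * solve(Psi) + diag(q))
  expect_equal(st$R_uu, K * solve(st$Sigma_u))
  expect_equal(st$R_zu, matrix(0, m, q))
})

test_that("e-step matches exact scalar Bayesian conditioning", {
  # q = m = 1, huge Psi so the mixing-matrix-uncertainty term vanishes:
  # posterior of u | z under z = A u + eps is N(A*omega*z/(A^2*omega + 1), .)
  K <- 5
  z <- matrix(c(0.4, -1.2, 2.0, 0.3, -0.7), 1)
  A <- matrix(0.8); omega <- 1 / 0.3                 # noise variance 0.3
  st <- make_state(A, 0.3, 1, matrix(1e14), z)
  st <- vbfa_e_step(z, st)
  oracle <- as.numeric(A) * omega * z / (as.numeric(A)^2 * omega + 1)
  expect_lt(max(abs(st$ubar - oracle)), 1e-12)
})

test_that("e-step moments are structurally valid on random instances", {
  set.seed(3)
  for (rep in 1:5) {
    m <- 8; q <- 3; K <- 30
    z <- matrix(rnorm(m * K), m, K)
    st <- make_state(matrix(rnorm(m * q), m, q), runif(m, 0.5, 2),
                     runif(q, 0.5, 2), rand_spd(q), z)
    st <- vbfa_e_step(z, st)
    expect_equal(st$R_uu, t(st$R_uu))
    expect_gte(min(eigen(st$R_uu, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    expect_gte(min(eigen(st$Sigma_u - diag(q), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("m-step closed forms: zero residuals and zero mixing matrix", {
  m <- 5; q <- 2; K <- 8
  z0 <- matrix(0, m, K)
  st <- make_state(matrix(rnorm(m * q), m, q), rep(1, m), rep(1, q), diag(q), z0)
  st <- vbfa_e_step(z0, st)
  st <- vbfa_m_step(z0, st)
  expect_equal(st$A, matrix(0, m, q))

  set.seed(4)
  z <- matrix(rnorm(m * K), m, K)
  st2 <- make_state(matrix(0, m, q), rep(1, m), rep(1, q), diag(q), z)
  st2 <- vbfa_e_step(z, st2)
  st2 <- vbfa_m_step(z, st2)
  # A enters the m-step as 0 via R_zu = 0 -> Omega^{-1} = per-sensor variances
  expect_equal(st2$Omega_inv, rowSums(z^2) / K)
})

test_that("noise covariance modes: plug-in evaluation and rank structure", {
  m <- 6; q <- 2; K <- 10
  # A = 0, fa_model -> diag(Omega_inv)
  st <- make_state(matrix(0, m, q), seq(0.5, 3, length.out = m), rep(1, q),
                   diag(q), matrix(rnorm(m * K), m, K))
  st$R_uu <- K * diag(q); st$n_iter <- 1L
  expect_equal(noise_covariance(st, "fa_model")$covariance,
               diag(seq(0.5, 3, length.out = m)))
  # A = 0, R_uu = K I, Psi = I, Omega_inv = 1 -> as_printed gives q * I
  st$Omega_inv <- rep(1, m); st$Psi <- diag(q)
  expect_equal(noise_covariance(st, "as_printed")$covariance, q * diag(m))
  # q < m, Omega_inv -> 0: numerical rank <= q
  set.seed(6)
  st$A <- matrix(rnorm(m * q), m, q)
  st$Omega_inv <- rep(1e-16, m)
  ev <- eigen(noise_covariance(st, "fa_model")$covariance, symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(ev[q + 1], 1e-10 * ev[1])
})

test_that("vbfa_fit: zero residuals, determinism, q = 0 reduction", {
  m <- 5; K <- 12
  z0 <- matrix(0, m, K)
  st <- vbfa_fit(z0, q = 2, seed = 9)
  expect_lte(st$n_iter, 2L)
  expect_equal(st$A, matrix(0, m, 2))

  set.seed(10)
  z <- matrix(rnorm(m * K), m, K)
  a <- vbfa_fit(z, q = 2, seed = 33)
  b <- vbfa_fit(z, q = 2, seed = 33)
  expect_identical(a, b)

  st0 <- vbfa_fit(z, q = 0)
  expect_equal(st0$Omega_inv, rowSums(z^2) / K)
  expect_equal(noise_covariance(st0)$kind, "learned-diagonal")
  expect_equal(noise_covariance(st0)$covariance, diag(rowSums(z^2) / K))

  expect_error(vbfa_fit(z, q = m + 1), "exceed")
  expect_error(vbfa_fit(z[, 1, drop = FALSE], q = 1), "K = 2")
})

test_that("fitted factor covariance beats the diagonal-only estimate", {
  set.seed(14)
  m <- 20; q_true <- 3; K <- 2000
  B <- matrix(rnorm(m * q_true), m, q_true)
  true_cov <- B %*% t(B) + diag(0.5, m)
  z <- B %*% matrix(rnorm(q_true * K), q_true, K) +
    matrix(rnorm(m * K, sd = sqrt(0.5)), m, K)
  st <- vbfa_fit(z, q = q_true, max_iter = 200, seed = 14)
  d_fa <- geodesic_distance(true_cov, noise_covariance(st)$covariance)
  d_diag <- geodesic_distance(true_cov, diag(rowSums(z^2) / K))
  expect_lt(d_fa, d_diag)
})
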