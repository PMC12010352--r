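grid_coords <- function(side) {
  as.matrix(expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side)))
}

test_that("compute_hits: delta map, zero map, degenerate input", {
  coords <- grid_coords(5)
  n <- nrow(coords)
  pm <- rep(0, n); pm[62] <- 1
  h <- compute_hits(pm, true_voxels = 62, coords)
  expect_equal(h$h_r, 1)
  expect_equal(h$f_r, 0)
  expect_warning(h0 <- compute_hits(rep(0, n), 62, coords), "zero")
  expect_equal(h0$h_r, 0)
  expect_equal(h0$f_r, 0)
  expect_error(compute_hits(pm, integer(0), coords), "nonempty")
})

test_that("compute_hits matches the brute-force neighbourhood oracle", {
  coords <- grid_coords(5)
  n <- nrow(coords)
  # hand-placed peaks
  pm <- rep(0, n)
  pm[c(1, 62, 120)] <- c(0.5, 1, 0.8)
  pm[c(10, 90)] <- c(0.02, 0.009)       # one passes the 1% rule, one fails
  truev <- c(62, 119)
  got <- compute_hits(pm, truev, coords)
  ref <- naive_hits(pm, truev, coords)
  expect_equal(got$h_r, ref$h_r)
  expect_equal(got$f_r, ref$f_r)
  expect_equal(got$candidates, sort(ref$candidates))
  # randomized cases
  set.seed(8)
  for (rep in 1:20) {
    pm <- abs(rnorm(n))^3
    truev <- sample(n, sample(1:5, 1))
    got <- compute_hits(pm, truev, coords)
    ref <- naive_hits(pm, truev, coords)
    expect_equal(got$h_r, ref$h_r)
    expect_equal(got$f_r, ref$f_r)
  }
})

test_that("A-prime closed forms and monotonicity", {
  expect_equal(froc_aprime(1, 0), 1)
  expect_equal(froc_aprime(0.4, 0.4), 0.5)
  expect_equal(froc_aprime(0, 1), 0)
  expect_equal(froc_aprime(0.6, 0.2, mode = "as_printed"), 0.9)
  expect_equal(froc_aprime(1, 1, mode = "as_printed"), 1.5)  # the printed form overflows
  expect_error(froc_aprime(1.2, 0), "0, 1")
  hs <- seq(0, 1, 0.25)
  expect_true(all(diff(sapply(hs, froc_aprime, f_r = 0.3)) > 0))
  expect_true(all(diff(sapply(hs, function(f) froc_aprime(0.7, f))) < 0))
})

test_that("time-course correlation: sign invariance and brute-force oracle", {
  scene <- tiny_scene(seed = 9)
  truth <- scene$truth
  coords <- scene$leadfield$voxel_coords
  n <- scene$leadfield$n
  # oracle estimate: truth placed at the true voxels
  xb <- matrix(0, n, scene$data$K)
  xb[truth$source_voxels, ] <- truth$source_timecourses
  hi <- compute_hits(rowMeans(xb^2), truth$source_voxels, coords)
  expect_equal(timecourse_correlation(xb, truth, hi, coords), 1)
  expect_equal(timecourse_correlation(-xb, truth, hi, coords), 1)
  # random reconstruction vs naive double-loop reference
  set.seed(10)
  for (rep in 1:5) {
    xr <- matrix(rnorm(n * scene$data$K), n)
    hr <- compute_hits(rowMeans(xr^2), truth$source_voxels, coords)
    expect_equal(timecourse_correlation(xr, truth, hr, coords),
                 naive_rbar(xr, truth, coords), tolerance = 1e-12)
  }
})

test_that("aggregate performance: closed forms, range checks", {
  expect_equal(aggregate_performance(1, 1, 1), 1)
  expect_equal(aggregate_performance(0.5, 0, 0.9), 0.25)
  expect_error(aggregate_performance(1.1, 0, 0), "0, 1")
  set.seed(11)
  for (rep in 1:50) {
    val <- aggregate_performance(runif(1), runif(1), runif(1))
    expect_gte(val, 0); expect_lte(val, 1)
  }
})

test_that("geodesic distance: identity, closed form, invariances", {
  S <- rand_spd(5)
  expect_equal(geodesic_distance(S, S), 0, tolerance = 1e-7)
  expect_equal(geodesic_distance(diag(4), exp(2) * diag(4)), 4)
  set.seed(12)
  for (rep in 1:10) {
    A <- rand_spd(4); B <- rand_spd(4)
    M <- matrix(rnorm(16), 4)
    while (abs(det(M)) < 1e-3) M <- matrix(rnorm(16), 4)
    expect_lt(abs(geodesic_distance(A, B) - geodesic_distance(B, A)), 1e-8)
    expect_lt(abs(geodesic_distance(M %*% A %*% t(M), M %*% B %*% t(M)) -
                  geodesic_distance(A, B)), 1e-8)
  }
  Ns <- matrix(1:16, 4)
  expect_error(geodesic_distance(Ns, diag(4)), "symmetric")
})

test_that("metrics are invariant to positive rescaling of the power map", {
  coords <- grid_coords(4)
  set.seed(13)
  pm <- abs(rnorm(nrow(coords)))
  truev <- c(5, 40)
  a <- compute_hits(pm, truev, coords)
  b <- compute_hits(1234.5 * pm, truev, coords)
  expect_identical(a[c("h_r", "f_r", "candidates")], b[c("h_r", "f_r", "candidates")])
})

test_that("froc curve is consistent with the fixed operating point", {
  coords <- grid_coords(5)
  set.seed(14)
  pm <- abs(rnorm(nrow(coords)))^3
  truev <- c(10, 70)
  fc <- froc_curve(pm, truev, coords, thresholds = c(0.01, seq(0, 1, 0.1)))
  op <- compute_hits(pm, truev, coords)
  row <- fc$curve[fc$curve$threshold == 0.01, ]
  expect_equal(row$h_r, op$h_r)
  expect_equal(row$f_r, op$f_r)
  expect_gte(fc$area, 0); expect_lte(fc$area, 1)
})
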