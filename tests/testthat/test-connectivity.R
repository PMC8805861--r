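test_that("lagged correlation matches hand cases and the slicing oracle", {
  ts <- region_ts(rbind(c(1, 0, 2, 0, 3, 0), c(0, 1, 0, 2, 0, 3)))
  L <- lagged_correlation(ts, 1)
  expect_equal(L$weights[1, 2], 1.0)   # identical segments after the shift

  set.seed(11)
  X <- matrix(rnorm(5 * 500), 5)
  L2 <- lagged_correlation(region_ts(X), 2)
  expect_equal(unname(L2$weights), oracle_lagged(X, 2), tolerance = 1e-12)
  expect_false(isSymmetric(L2$weights))

  # d = 0 coincides with the classical Pearson correlation matrix
  L0 <- lagged_correlation(region_ts(X), 0)
  expect_equal(unname(L0$weights), unname(cor(t(X))), tolerance = 1e-12)

  expect_error(lagged_correlation(region_ts(X[, 1:5]), 4), "too large")
  expect_error(lagged_correlation(region_ts(X), -1), "nonnegative")
})

test_that("zero-variance segments yield 0 entries with a warning", {
  X <- rbind(rep(1, 20), rnorm(20))
  expect_warning(L <- lagged_correlation(region_ts(X), 1), "zero-variance")
  expect_equal(unname(L$weights[1, ]), c(0, 0))
  expect_warning(z <- zero_lag_correlation(region_ts(X)), "constant")
  expect_equal(unname(z$weights[1, 2]), 0)
})

test_that("antisymmetric/symmetric parts obey the exact decomposition", {
  set.seed(7)
  for (rep in 1:20) {
    X <- matrix(rnorm(6 * 120), 6)
    L <- lagged_correlation(region_ts(X), sample(0:4, 1))
    A <- antisymmetric_part(L, clip = FALSE)
    S <- symmetric_part(L, clip = FALSE)
    expect_equal(A$weights + S$weights, 2 * L$weights, tolerance = 1e-14)
    expect_equal(t(A$weights), -A$weights, tolerance = 1e-14)
    expect_equal(t(S$weights), S$weights, tolerance = 1e-14)
  }
})

test_that("2x2 hand cases for the decomposition and clipping", {
  L <- conn_matrix(matrix(c(0, 0.8, 0.2, 0), 2, 2, byrow = TRUE), "lagged")
  A_raw <- antisymmetric_part(L, clip = FALSE)
  expect_equal(unname(A_raw$weights),
               matrix(c(0, 0.6, -0.6, 0), 2, 2, byrow = TRUE))
  A <- antisymmetric_part(L)
  expect_equal(unname(A$weights), matrix(c(0, 0.6, 0, 0), 2, 2, byrow = TRUE))
  expect_true(A$clipped)
  S <- symmetric_part(L)
  expect_equal(unname(S$weights), matrix(c(0, 1, 1, 0), 2, 2))

  # symmetric input -> zero antisymmetric part
  Ls <- conn_matrix(matrix(c(0, 0.4, 0.4, 0), 2, 2), "lagged")
  expect_equal(unname(antisymmetric_part(Ls)$weights), matrix(0, 2, 2))
  # antisymmetric input -> zero symmetric part
  La <- conn_matrix(matrix(c(0, 0.4, -0.4, 0), 2, 2), "lagged")
  expect_equal(unname(symmetric_part(La)$weights), matrix(0, 2, 2))
})

test_that("decomposition refuses clipped or non-lagged inputs", {
  L <- clip_connectivity(conn_matrix(matrix(rnorm(9), 3), "lagged"))
  expect_error(antisymmetric_part(L), "unclipped")
  z <- conn_matrix(diag(3) * 0, "zerolag")
  expect_error(symmetric_part(z), "lagged")
})

test_that("zero-lag correlation equals lagged at d = 0 and clips negatives", {
  set.seed(3)
  X <- matrix(rnorm(8 * 200), 8)
  z <- zero_lag_correlation(region_ts(X), clip = FALSE)
  L0 <- lagged_correlation(region_ts(X), 0)
  expect_equal(z$weights, L0$weights, tolerance = 1e-12)

  x <- rnorm(50)
  ts <- region_ts(matrix(c(x, -x, 2 * x + 3), nrow = 3, byrow = TRUE))
  zc <- zero_lag_correlation(ts)
  expect_equal(unname(zc$weights[1, 2]), 0)         # perfect anticorrelation clipped
  expect_equal(unname(zc$weights[1, 3]), 1)         # affine invariance
  expect_equal(unname(diag(zc$weights)), rep(0, 3)) # self-connections zeroed
})

test_that("correlations lie in [-1,1] signed and [0,?] clipped", {
  set.seed(21)
  for (d in c(0, 1, 3)) {
    X <- matrix(rnorm(6 * 80), 6)
    L <- lagged_correlation(region_ts(X), d)
    expect_true(all(L$weights >= -1 & L$weights <= 1))
    A <- antisymmetric_part(L)
    expect_true(all(A$weights >= 0 & A$weights <= 2))
  }
})

test_that("group average is the elementwise mean with method checks", {
  m1 <- conn_matrix(matrix(1:9, 3), "lagged", lag = 1L)
  m2 <- conn_matrix(matrix(9:1, 3), "lagged", lag = 1L)
  avg <- group_average_matrix(list(m1, m2))
  expect_equal(unname(avg$weights), matrix(5, 3, 3))
  expect_equal(unname(group_average_matrix(list(m1, m1))$weights),
               unname(m1$weights))
  m3 <- conn_matrix(matrix(1:9, 3), "zerolag")
  expect_error(group_average_matrix(list(m1, m3)), "method")
})

test_that("weight histogram excludes zeros by default and counts correctly", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- w[3, 4] <- 0.5
  mat <- conn_matrix(w, "antisymmetric", clipped = TRUE)
  h <- weight_histogram(mat, n_bins = 5)
  expect_equal(sum(h$counts), 3)          # zeros excluded
  expect_equal(sum(h$counts > 0), 1)      # all-equal weights: one occupied bin
  h2 <- weight_histogram(mat, n_bins = 5, include_zeros = TRUE)
  expect_equal(sum(h2$counts), 12)        # n(n-1) off-diagonal entries
  expect_error(weight_histogram(mat, n_bins = 0), "n_bins")
})
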