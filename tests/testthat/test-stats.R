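test_that("residualization removes covariate effects", {
  set.seed(1)
  n <- 60
  age <- rnorm(n, 65, 8)
  # orthogonal covariate: output is just the demeaned input
  v <- rnorm(n)
  X <- matrix(rnorm(n), dimnames = list(NULL, "z"))
  r <- residualize(v, NULL)
  expect_equal(r, v - mean(v))
  # exact linear function of covariates -> all-zero residuals
  v2 <- 2 * age - 5
  expect_equal(residualize(v2, data.frame(age = age)), rep(0, n),
               tolerance = 1e-10)
  # planted group effect survives removal of a planted age effect
  grp <- rep(0:1, each = n / 2)
  v3 <- 0.5 * age + 2 * grp + rnorm(n, sd = 0.3)
  r3 <- residualize(v3, data.frame(age = age))
  est <- mean(r3[grp == 1]) - mean(r3[grp == 0])
  expect_equal(est, 2, tolerance = 0.3)
  # rank deficiency names the collinear column
  expect_error(residualize(v, data.frame(a = age, b = 2 * age)),
               "rank deficient")
})

test_that("permutation test is exact on degenerate and identical data", {
  set.seed(2)
  vals <- matrix(rnorm(40), 20, 2)
  g <- factor(rep(c("A", "B"), 10))
  # identical values in both groups: permuting labels can never exceed |obs|=0
  same <- matrix(1, 20, 2) * rnorm(1)
  res <- permutation_test_global(cbind(c(same[, 1])), g, n_perm = 500, seed = 3)
  expect_equal(res$p, 1)
  expect_warning(permutation_test_global(vals, g, n_perm = 50, seed = 1),
                 "coarse")
  expect_error(permutation_test_global(vals, factor(rep("A", 20)),
                                       n_perm = 200, seed = 1), "two groups")
})

test_that("permutation p-values are reproducible and order-insensitive", {
  set.seed(6)
  n <- 30
  vals <- matrix(rnorm(n * 3), n, 3)
  g <- factor(rep(c("A", "B"), c(12, 18)))
  r1 <- permutation_test_global(vals, g, n_perm = 2000, seed = 11)
  r2 <- permutation_test_global(vals, g, n_perm = 2000, seed = 11)
  expect_identical(r1$p, r2$p)
  perm <- sample(n)
  r3 <- permutation_test_global(vals[perm, ], g[perm], n_perm = 2000, seed = 11)
  # same data in a different subject order: p agrees within Monte-Carlo error
  expect_equal(r1$p, r3$p, tolerance = 0.05)
})

test_that("a strong group difference is detected with high power", {
  set.seed(8)
  hits <- 0
  for (r in 1:40) {
    v <- c(rnorm(15), rnorm(95) + 2)   # 2 SD shift at the clinical design size
    g <- factor(rep(c("A", "B"), c(15, 95)))
    res <- permutation_test_global(cbind(v), g, n_perm = 500, seed = r)
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
})

test_that("nodal AUC test pinpoints a planted region and preserves counts", {
  set.seed(9)
  n <- 40; k <- 8
  vals <- matrix(rnorm(n * k), n, k,
                 dimnames = list(NULL, paste0("R", 1:k)))
  g <- factor(rep(c("A", "B"), each = 20))
  vals[g == "B", 3] <- vals[g == "B", 3] + 1.5
  res <- permutation_test_nodal_auc(vals, g, n_perm = 1000, seed = 4)
  expect_equal(nrow(res), k)
  expect_equal(which.min(res$p), 3)
  expect_true(res$significant[3])
})

test_that("null nodal p-values are approximately uniform", {
  set.seed(10)
  ps <- c()
  for (r in 1:25) {
    vals <- matrix(rnorm(30 * 6), 30, 6)
    g <- factor(rep(c("A", "B"), each = 15))
    res <- permutation_test_nodal_auc(vals, g, n_perm = 400, seed = r)
    ps <- c(ps, res$p)
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH FDR matches the hand case and a brute-force step-up oracle", {
  r <- fdr_bh(c(0.001, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected))   # max p = 0.04 <= 0.05 * 4/4
  expect_false(any(fdr_bh(rep(1, 10), q = 0.05)$rejected))
  expect_length(fdr_bh(numeric(0))$rejected, 0)
  set.seed(12)
  for (rep in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, q)$rejected, oracle_bh(p, q))
  }
})

test_that("adding a pure-noise covariate barely moves p", {
  set.seed(14)
  n <- 50
  v <- c(rnorm(25), rnorm(25) + 0.8)
  g <- factor(rep(c("A", "B"), each = 25))
  p0 <- permutation_test_global(cbind(v), g, n_perm = 4000, seed = 5)$p
  p1 <- permutation_test_global(cbind(v), g,
                                covariates = data.frame(noise = rnorm(n)),
                                n_perm = 4000, seed = 5)$p
  expect_equal(p0, p1, tolerance = 0.02 + 3 * sqrt(p0 * (1 - p0) / 4000))
})

test_that("clinical correlation recovers exact and planted associations", {
  set.seed(16)
  v <- rnorm(40)
  expect_equal(clinical_correlation(v, 3 * v + 2, n_perm = 200, seed = 1)$r, 1)
  expect_error(clinical_correlation(v, rep(1, 40)), "constant")
  expect_error(clinical_correlation(v[1:3], v[1:3]), "4 complete pairs")
  # independent pairs: small |r|, p not extreme
  res <- clinical_correlation(rnorm(95), rnorm(95), n_perm = 1000, seed = 2)
  expect_lt(abs(res$r), 0.35)
  # planted r = -0.35 at n = 95 recovered within +/- 0.1 most of the time
  hits <- 0
  for (r in 1:30) {
    x <- rnorm(95)
    y <- -0.35 * x + sqrt(1 - 0.35^2) * rnorm(95)
    est <- clinical_correlation(x, y, n_perm = 200, seed = r)$r
    if (abs(est + 0.35) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.6)
})
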