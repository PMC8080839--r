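test_that("lag-1 autocorrelation matches the direct formula and AR(1) theory", {
  expect_equal(lag1_autocorrelation(c(1, -1, 1, -1)), -0.75)
  expect_error(lag1_autocorrelation(rep(2, 10)),
               class = "ewsbench_degenerate_error")
  expect_error(lag1_autocorrelation(c(1, 2)),
               class = "ewsbench_parameter_error")

  x <- ar1_series(20000, phi = 0.8, seed = 2)
  expect_equal(lag1_autocorrelation(x), 0.8, tolerance = 0.02)

  set.seed(4)
  z <- rnorm(20000)
  expect_lt(abs(lag1_autocorrelation(z)), 0.03)
})

test_that("covariance matrix agrees with a brute-force double loop", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  C <- covariance_matrix(X)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      oracle[i, j] <- sum((X[, i] - mean(X[, i])) *
                            (X[, j] - mean(X[, j]))) / (nrow(X) - 1)
    }
  }
  expect_equal(unname(C), oracle, tolerance = 1e-12)

  # two identical columns give a rank-1 matrix with equal entries
  Y <- cbind(X[, 1], X[, 1])
  CY <- covariance_matrix(Y)
  expect_equal(max(CY) - min(CY), 0, tolerance = 1e-14)
  expect_equal(var(X[, 1]), CY[1, 1])
})

test_that("whitening produces identity covariance and flags degeneracy", {
  set.seed(20)
  X <- matrix(rnorm(4000), 1000, 4) %*% matrix(rnorm(16), 4, 4)
  w <- whiten(X)
  expect_equal(unname(cov(w$Y)), diag(4), tolerance = 1e-8)

  # 1 variable: scalar 1/sd
  x1 <- matrix(rnorm(500, sd = 3), ncol = 1)
  w1 <- whiten(x1)
  expect_equal(abs(w1$transform[1, 1]), 1 / sd(x1), tolerance = 1e-10)

  # rank-deficient input is reduced with a warning
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  expect_warning(wd <- whiten(Xd), "rank-deficient")
  expect_equal(ncol(wd$Y), 2)
})

test_that("MAF decomposition: white-noise eigenvalues, direction recovery, generalized-eigenproblem identity", {
  set.seed(30)
  Z <- matrix(rnorm(30000), 10000, 3)
  m <- maf_decomposition(Z)
  # differences of unit-variance white noise have variance 2
  expect_equal(m$eigenvalues, rep(2, 3), tolerance = 0.1)

  # a hidden slow AR(1) axis is recovered after random rotation
  ar <- ar1_series(8000, phi = 0.9, seed = 31)
  wn <- rnorm(8000)
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  X <- cbind(ar, wn) %*% Q
  mx <- maf_decomposition(X)
  proj <- sweep(X, 2, colMeans(X)) %*% mx$weights[, 1]
  expect_gt(abs(cor(proj, ar)), 0.95)

  # whiten-then-difference equals the generalized eigenproblem
  # cov(diff(X)) v = lambda cov(X) v, solved through a Cholesky reduction
  C <- cov(X)
  D <- cov(diff(X))
  L <- t(chol(C))
  M <- solve(L, t(solve(L, t(D))))
  gev <- sort(eigen((M + t(M)) / 2, symmetric = TRUE)$values)
  expect_equal(mx$eigenvalues, gev, tolerance = 1e-8)
})

test_that("KSG mutual information matches independence and the Gaussian closed form", {
  set.seed(40)
  x <- matrix(rnorm(5000), ncol = 1)
  y <- matrix(rnorm(5000), ncol = 1)
  expect_lt(abs(ksg_mutual_information(x, y)), 0.05)

  rho <- 0.6
  n <- 10000
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  mi <- ksg_mutual_information(matrix(z1), matrix(z2))
  expect_lt(abs(mi - (-0.5 * log2(1 - rho^2))), 0.05)

  # self-information diverges with sample size
  mi_small <- ksg_mutual_information(matrix(z1[1:500]), matrix(z1[1:500]))
  mi_large <- ksg_mutual_information(matrix(z1[1:5000]), matrix(z1[1:5000]))
  expect_gt(mi_small, 1)
  expect_gt(mi_large, mi_small)
})

test_that("indicator catalogue: constructed covariance cases and order relations", {
  set.seed(50)
  # two perfectly anticorrelated columns
  x <- rnorm(200)
  anti <- cbind(x, -x) + 0  # exact anticorrelation
  expect_equal(compute_indicator("avg_cross_correlation", anti)$value, 1)

  # diagonal covariance diag(3, 1) built from orthogonal columns
  n <- 400
  a <- rep(c(1, 1, -1, -1), n / 4) * sqrt(3)
  b <- rep(c(1, -1, 1, -1), n / 4)
  X <- cbind(a, b) * sqrt((n - 1) / n)  # divisor T-1 exact
  expect_equal(compute_indicator("explained_variance", X)$value, 0.75,
               tolerance = 1e-10)
  expect_equal(compute_indicator("pca_variance", X)$value, 3,
               tolerance = 1e-10)
  expect_equal(compute_indicator("max_covariance", X)$value, 3,
               tolerance = 1e-10)

  Y <- matrix(rnorm(2000), 500, 4)
  expect_gte(compute_indicator("node_max_variance", Y)$value,
             compute_indicator("avg_variance", Y)$value)
  expect_gte(compute_indicator("node_max_autocorrelation", Y)$value,
             compute_indicator("avg_autocorrelation", Y)$value)
  ev <- compute_indicator("explained_variance", Y)$value
  expect_true(ev > 0 && ev <= 1)
  cc <- compute_indicator("avg_cross_correlation", Y)$value
  expect_true(cc >= 0 && cc <= 1)
})

test_that("pca_variance equals the top covariance eigenvalue by an independent route", {
  set.seed(60)
  X <- matrix(rnorm(3000), 1000, 3) %*% matrix(rnorm(9), 3, 3)
  pv <- compute_indicator("pca_variance", X)$value
  # independent route: variance of the projection on the leading eigenvector
  v1 <- eigen(cov(X), symmetric = TRUE)$vectors[, 1]
  expect_equal(pv, var(as.vector(sweep(X, 2, colMeans(X)) %*% v1)),
               tolerance = 1e-8)
  expect_equal(pv, max(eigen(cov(X), only.values = TRUE)$values),
               tolerance = 1e-10)
})

test_that("MAF autocorrelation dominates per-variable autocorrelation on linear-Gaussian data", {
  for (seed in c(70, 71, 72)) {
    ar <- ar1_series(6000, phi = 0.85, seed = seed)
    mix <- cbind(ar + 0.5 * rnorm(6000), 0.7 * ar + rnorm(6000))
    maf_ac <- compute_indicator("maf_autocorrelation", mix)$value
    node_ac <- compute_indicator("node_max_autocorrelation", mix)$value
    expect_gte(maf_ac, node_ac - 0.02)
  }
})

test_that("catalogue errors and univariate degradation behave as documented", {
  expect_error(compute_indicator("not_an_indicator", matrix(rnorm(40), 20)),
               class = "ewsbench_catalogue_error")
  x1 <- matrix(rnorm(100), ncol = 1)
  expect_error(compute_indicator("avg_cross_correlation", x1),
               class = "ewsbench_parameter_error")
  expect_error(compute_indicator("maf_eigenvalue", x1),
               class = "ewsbench_parameter_error")
  # univariate-capable indicators still work on one column
  expect_true(is.finite(compute_indicator("avg_variance", x1)$value))
  expect_true(is.finite(compute_indicator("mutual_information", x1)$value))

  # constant column inside an aggregate contributes 0 with a warning
  Xc <- cbind(rnorm(50), rep(1, 50))
  expect_warning(v <- compute_indicator("avg_autocorrelation", Xc)$value,
                 "constant")
  expect_true(is.finite(v))
})

test_that("indicator battery returns a long-format table with orientations", {
  set.seed(80)
  X <- mvts(matrix(rnorm(800), 200, 4), sampling_interval = 0.1)
  tab <- compute_indicators(X)
  expect_equal(nrow(tab), 13)
  expect_setequal(tab$indicator, indicator_names())
  expect_equal(tab$orientation[tab$indicator == "maf_eigenvalue"],
               "decreases_toward_transition")
  expect_equal(sum(tab$orientation == "increases_toward_transition"), 12)
})
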