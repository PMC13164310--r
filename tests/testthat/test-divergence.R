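test_that("KL divergence of identical summaries is zero", {
  s <- gaussian_summary(c(1, -2, 0.5), random_pd(3, 1))
  expect_equal(gaussian_kl(s, s), 0, tolerance = 1e-10)
})

test_that("univariate KL matches the closed form", {
  a <- scalar_summary(2, 1)
  b <- scalar_summary(0, 1)
  expect_equal(gaussian_kl(a, b), 2)     # 0.5 * (0 - 1 + 1 + 4)
  a2 <- scalar_summary(1, 2)
  b2 <- scalar_summary(-1, 0.5)
  expect_equal(gaussian_kl(a2, b2), kl_1d(1, 2, -1, 0.5), tolerance = 1e-12)
})

test_that("KL matches a Monte Carlo estimate of the defining integral", {
  set.seed(99)
  p <- 5
  a <- gaussian_summary(rnorm(p), random_pd(p, 2))
  b <- gaussian_summary(rnorm(p), random_pd(p, 3))
  n_mc <- 1e6
  # sample x ~ a, average log f_a(x) - log f_b(x)
  Ra <- chol(a$sigma)
  X <- sweep(matrix(rnorm(n_mc * p), n_mc, p) %*% Ra, 2L, a$mu, "+")
  log_density <- function(X, mu, sigma) {
    R <- chol(sigma)
    Z <- forwardsolve(t(R), t(sweep(X, 2L, mu)))
    -0.5 * colSums(Z^2) - sum(log(diag(R))) - 0.5 * p * log(2 * pi)
  }
  diffs <- log_density(X, a$mu, a$sigma) - log_density(X, b$mu, b$sigma)
  mc <- mean(diffs)
  se <- stats::sd(diffs) / sqrt(n_mc)
  expect_lt(abs(gaussian_kl(a, b) - mc), 3 * se)
})

test_that("KL is nonnegative, zero only at equality, and asymmetric", {
  set.seed(7)
  for (i in 1:20) {
    p <- sample(2:6, 1)
    a <- gaussian_summary(rnorm(p), random_pd(p, i))
    b <- gaussian_summary(rnorm(p), random_pd(p, i + 100))
    kab <- gaussian_kl(a, b)
    kba <- gaussian_kl(b, a)
    expect_gte(kab, 0)
    expect_gt(kab, 1e-4)                     # distinct parameters
    expect_gt(abs(kab - kba), 1e-8)          # no silent symmetrisation
  }
})

test_that("KL is invariant under a shared orthogonal rotation", {
  set.seed(13)
  p <- 4
  a <- gaussian_summary(rnorm(p), random_pd(p, 4))
  b <- gaussian_summary(rnorm(p), random_pd(p, 5))
  Q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  ar <- gaussian_summary(drop(Q %*% a$mu), Q %*% a$sigma %*% t(Q))
  br <- gaussian_summary(drop(Q %*% b$mu), Q %*% b$sigma %*% t(Q))
  expect_equal(gaussian_kl(a, b), gaussian_kl(ar, br), tolerance = 1e-8)
})

test_that("dimension mismatches and invalid covariances are rejected", {
  a <- scalar_summary(0)
  b <- gaussian_summary(c(0, 0), diag(2))
  expect_error(gaussian_kl(a, b), "dimension")
  expect_error(gaussian_summary(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(gaussian_summary(0, matrix(1:4, 2)), "disagree|symmetric")
})

test_that("repair_pd clips eigenvalues and preserves PD inputs", {
  x <- random_pd(4, 21)
  expect_equal(repair_pd(x), x, tolerance = 1e-12)
  bad <- diag(c(1, 1, -0.5, 2))
  fixed <- repair_pd(bad, eps = 1e-4)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-4 - 1e-12)
})

test_that("block summaries restrict, invert and optionally standardize", {
  om <- unclass(adjacency_to_precision(generate_adjacency(6, "band")))
  net <- structure(list(omega = om, sigma = solve(om), cell_line = 1L),
                   class = "cell_line_network")
  x <- rnorm(6)
  genes <- 2:4
  raw <- block_summary(net, x, genes, standardize = FALSE)
  expect_equal(raw$mu, x[genes])
  expect_equal(raw$sigma, solve(om[genes, genes]), tolerance = 1e-8)
  std <- block_summary(net, x, genes, standardize = TRUE)
  expect_equal(diag(std$sigma), rep(1, 3))
  s <- sqrt(diag(solve(om[genes, genes])))
  expect_equal(std$mu, x[genes] / s)
  # covariance-based restriction takes the submatrix of sigma
  cov_based <- block_summary(net, x, genes, from = "covariance",
                             standardize = FALSE)
  expect_equal(cov_based$sigma, solve(om)[genes, genes], tolerance = 1e-8)
})
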