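test_that("kernel weights have closed-form behaviour", {
  m <- draw_modulators(50, seed = 1)
  w <- kernel_weights(m, 25, bandwidth = 1e6)
  expect_equal(w, rep(1, 50), tolerance = 1e-6)    # h -> Inf: uniform
  w0 <- kernel_weights(m, 25, bandwidth = 1e-4)
  expect_equal(which.max(w0), 25)                  # h -> 0: concentrates
  expect_gt(w0[25] / sum(w0), 0.99)
  # at distance exactly h the weight ratio to the self-weight is exp(-1/2)
  mm <- c(0, 1, 5)
  wh <- kernel_weights(mm, 1, bandwidth = 1)
  expect_equal(wh[2] / wh[1], exp(-0.5), tolerance = 1e-12)
  expect_equal(sum(wh), 3)
  expect_error(kernel_weights(m, 1, bandwidth = 0), "positive")
})

test_that("a huge penalty shrinks all coefficients to zero", {
  set.seed(2)
  X <- matrix(rnorm(50 * 6), 50, 6)
  f <- fit_nodewise(X, rep(1, 50), target = 1, lambda = 10)
  expect_true(all(f$beta == 0))
  wvar <- mean((X[, 1] - mean(X[, 1]))^2)
  expect_equal(f$sigma2, wvar, tolerance = 1e-6)
})

test_that("lambda = 0 with uniform weights reproduces least squares", {
  set.seed(3)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4)
  X[, 1] <- 0.6 * X[, 2] - 0.3 * X[, 3] + rnorm(n, sd = 0.5)
  f <- fit_nodewise(X, rep(1, n), target = 1, lambda = 0)
  ols <- stats::lm(X[, 1] ~ X[, -1])
  expect_equal(unname(f$beta), unname(stats::coef(ols)[-1]),
               tolerance = 1e-4)
})

test_that("a 3-gene chain is recovered at small lambda", {
  set.seed(4)
  n <- 500
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n, sd = sqrt(1 - 0.8^2))
  x3 <- rnorm(n)
  X <- cbind(x1, x2, x3)
  f <- fit_nodewise(X, rep(1, n), target = 2, lambda = 0.02)
  expect_equal(unname(f$beta["x1"]), 0.8, tolerance = 0.08)
  expect_lt(abs(f$beta["x3"]), 0.05)
})

test_that("weighted lasso agrees with the glmnet oracle", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 120
  p <- 12
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- 0.7 * X[, 2] - 0.5 * X[, 5] + rnorm(n, sd = 0.6)
  m <- draw_modulators(n)
  w <- kernel_weights(m, 60, bandwidth = 0.8)
  for (lambda in c(0.05, 0.15, 0.3)) {
    f <- fit_nodewise(X, w, target = 1, lambda = lambda)
    # same problem in glmnet parameterisation: weights sum to 1,
    # penalty on weighted-standardized predictors
    om <- w / sum(w)
    ctr <- colSums(X * om)
    Xc <- sweep(X, 2L, ctr)
    s <- sqrt(colSums(Xc^2 * om))
    Z <- sweep(Xc, 2L, s, "/")
    g <- glmnet::glmnet(Z[, -1], Z[, 1], weights = om, lambda = lambda,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-12)
    beta_or <- as.numeric(g$beta) * s[1] / s[-1]
    expect_equal(unname(f$beta), beta_or, tolerance = 1e-4)
  }
})

test_that("assemble_precision applies the nodewise arithmetic and symmetrises", {
  # all beta zero, unit variances -> identity
  fits <- lapply(1:4, function(l) list(target = l, beta = rep(0, 3),
                                       sigma2 = 1))
  net <- assemble_precision(fits)
  expect_equal(net$omega, diag(4))
  expect_equal(net$sigma, diag(4))
  # asymmetric raw entries average: (1,2) built from -b12/s1 and -b21/s2
  beta <- matrix(0, 2, 2)
  beta[1, 2] <- 0.4
  beta[2, 1] <- 0.6
  net2 <- assemble_precision(list(beta = beta, sigma2 = c(1, 1)))
  expect_equal(net2$omega[1, 2], -0.5)
  expect_equal(net2$omega, t(net2$omega))
  expect_equal(net2$sigma %*% net2$omega, diag(2), tolerance = 1e-8)
})

test_that("estimated networks recover a banded support (edge F1 > 0.9)", {
  set.seed(6)
  p <- 10
  om <- adjacency_to_precision(generate_adjacency(p, "band"),
                               edge_weight = 0.4)
  X <- celldgn:::rmvn_scaled(om, rep(1, 500), mu = 0)
  nets <- estimate_networks(X, modulator = seq_len(500), cells = 250L,
                            bandwidth = 1e6)
  est <- nets[["250"]]$omega
  keep <- abs(est) > 0.05 * max(abs(est - diag(diag(est))))
  diag(keep) <- FALSE
  truth <- precision_support(om) == 1
  tp <- sum(keep & truth) / 2
  prec <- tp / (sum(keep) / 2)
  rec <- tp / (sum(truth) / 2)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gt(f1, 0.9)
  # recovered edge signs match the generating precision's signs
  expect_true(all(sign(est[keep & truth]) ==
                    sign(unclass(om)[keep & truth])))
})

test_that("uniform weights give near-identical networks across cells", {
  set.seed(7)
  om <- adjacency_to_precision(generate_adjacency(8, "random", seed = 1))
  X <- celldgn:::rmvn_scaled(om, rep(1, 300), mu = 0)
  # amplitude rescaling is per-cell, so compare the estimator proper
  nets <- estimate_networks(X, modulator = seq_len(300),
                            cells = c(50L, 250L), bandwidth = 1e6,
                            amplitude_rescale = FALSE)
  expect_equal(nets[["50"]]$omega, nets[["250"]]$omega, tolerance = 1e-6)
  # with rescaling the two networks agree up to their scalar row scales
  nets2 <- estimate_networks(X, modulator = seq_len(300),
                             cells = c(50L, 250L), bandwidth = 1e6)
  r <- nets2[["50"]]$omega / nets2[["250"]]$omega
  expect_lt(stats::sd(r[nets2[["50"]]$omega != 0]), 1e-6)
})

test_that("every estimated precision matrix is symmetric PD with inverse", {
  cfg <- tiny_config(seed = 8)
  panel <- simulate_panel(cfg)
  nets <- estimate_networks(panel$expression, panel$modulator,
                            cells = c(1L, 18L, 36L))
  for (net in nets) {
    expect_equal(net$omega, t(net$omega))
    expect_true(is_positive_definite(net$omega))
    expect_equal(unname(net$omega %*% net$sigma), diag(nrow(net$omega)),
                 tolerance = 1e-6)
  }
})
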