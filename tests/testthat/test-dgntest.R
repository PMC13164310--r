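test_that("between/within means reduce to scalar KL arithmetic", {
  # cells 1-3: phenotype A; cells 4-5: phenotype B (query = 5)
  s <- list(scalar_summary(0), scalar_summary(1), scalar_summary(2),
            scalar_summary(4), scalar_summary(5))
  expected_between <- mean(c(kl_1d(5, 1, 0, 1), kl_1d(5, 1, 1, 1),
                             kl_1d(5, 1, 2, 1)))
  expect_equal(d_between(5, s, 1:3), expected_between)
  expected_within <- mean(c(kl_1d(5, 1, 4, 1), 0))  # self term included
  expect_equal(d_within(5, s, 4:5), expected_within)
  expect_equal(kl_ratio(5, s, 1:3, 4:5),
               expected_between / expected_within)
  expect_error(d_between(5, s, integer(0)), "nonempty")
  expect_error(d_between(1, s, 1:3), "must not belong")
})

test_that("identical networks give zero divergences and a degenerate ratio", {
  s <- replicate(4, scalar_summary(1), simplify = FALSE)
  expect_equal(d_between(4, s, 1:2), 0)
  expect_equal(d_within(4, s, 3:4), 0)
  expect_warning(r <- kl_ratio(4, s, 1:2, 3:4), "degenerate")
  expect_identical(r, Inf)
})

test_that("hand-built case with d_between 4 and d_within 2 gives ratio 2", {
  # query var 1 at 0; A cell and one B cell both at distance 2*sqrt(2),
  # each KL = 4; the self term drags the within average to 2
  s <- list(scalar_summary(2 * sqrt(2)), scalar_summary(2 * sqrt(2)),
            scalar_summary(0))
  expect_equal(d_between(3, s, 1), 4)
  expect_equal(d_within(3, s, 2:3), 2)
  expect_equal(kl_ratio(3, s, 1, 2:3), 2)
})

test_that("permutation p-values hit the exact boundary cases", {
  # A cells far from the query, same-phenotype cells close: the observed
  # ratio beats (almost) every permuted one; the p-value follows the
  # printed counting rule exactly and can reach 0
  s <- c(replicate(10, scalar_summary(10), simplify = FALSE),
         replicate(4, scalar_summary(0.3), simplify = FALSE),
         list(scalar_summary(0)))
  res <- permutation_test(15, s, 1:10, 11:15, T = 50, seed = 1)
  expect_equal(res$p_value, sum(res$ratio <= res$perm_stats) / 50)
  expect_equal(res$p_value, 0)
  expect_true(res$significant)
  # reversed orientation: query sits inside A's cloud, far from B -> p = 1
  s2 <- list(scalar_summary(0), scalar_summary(0), scalar_summary(0),
             scalar_summary(10), scalar_summary(0.1))
  res2 <- permutation_test(5, s2, 1:3, 4:5, T = 50, seed = 1)
  expect_equal(res2$p_value, 1)
  expect_error(permutation_test(5, s, 1:3, 4:5, T = 0), "at least 1")
  expect_error(permutation_test(1, s, 2:3, 4:5), "belong")
})

test_that("permutation results are reproducible given seed and T", {
  set.seed(42)
  s <- lapply(1:10, function(i) scalar_summary(rnorm(1), 1 + runif(1)))
  r1 <- permutation_test(10, s, 1:5, 6:10, T = 200, seed = 7)
  r2 <- permutation_test(10, s, 1:5, 6:10, T = 200, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$perm_stats, r2$perm_stats)
  # smoothed variant never returns exactly zero
  r3 <- permutation_test(10, s, 1:5, 6:10, T = 200, seed = 7, smooth = TRUE)
  expect_gt(r3$p_value, 0)
  expect_equal(r3$p_value, (1 + sum(r1$ratio <= r1$perm_stats)) / 201)
})

test_that("p-values are near-uniform for exchangeable summaries", {
  # exchangeable scalar summaries: rejection at alpha should be ~ alpha
  set.seed(11)
  pvals <- replicate(400, {
    s <- lapply(1:16, function(i) scalar_summary(rnorm(1), 1))
    permutation_test(16, s, 1:8, 9:16, T = 99)$p_value
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
  expect_lt(abs(mean(pvals < 0.25) - 0.25), 0.06)
  expect_lt(abs(mean(pvals < 0.5) - 0.5), 0.07)
})

test_that("call_dgns tests every block and skips singletons", {
  cfg <- tiny_config(mu_B = 5, seed = 12)
  panel <- simulate_panel(cfg)
  ph <- pheno_indices(panel)
  nets <- estimate_networks(panel$expression, panel$modulator,
                            cells = sort(c(ph$A, ph$B)), bandwidth = 0.3)
  calls <- call_dgns(nets, panel$expression, panel$partition, ph$A, ph$B,
                     modulator = panel$modulator, T = 200, seed = 3)
  expect_s3_class(calls, "dgn_calls")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$query, rep(ph$B[which.max(panel$modulator[ph$B])], 2))
  # strong mean shift: the specific block must be called
  expect_true(calls$significant[2])
  # identical rerun is bit-identical
  calls2 <- call_dgns(nets, panel$expression, panel$partition, ph$A, ph$B,
                      modulator = panel$modulator, T = 200, seed = 3)
  expect_identical(calls$p_value, calls2$p_value)
  # singleton blocks are skipped with a message
  part <- c(panel$partition, list(sub_singleton = 1L))
  expect_message(
    calls3 <- call_dgns(nets, panel$expression, part, ph$A, ph$B,
                        modulator = panel$modulator, T = 50, seed = 3),
    "skipped")
  expect_equal(nrow(calls3), 2)
})

test_that("median-over-queries aggregation works and stays reproducible", {
  cfg <- tiny_config(mu_B = 5, seed = 13)
  panel <- simulate_panel(cfg)
  ph <- pheno_indices(panel)
  nets <- estimate_networks(panel$expression, panel$modulator,
                            cells = sort(c(ph$A, ph$B)), bandwidth = 0.3)
  calls <- call_dgns(nets, panel$expression, panel$partition, ph$A, ph$B,
                     modulator = panel$modulator, T = 100, seed = 5,
                     query_policy = "median_all")
  expect_equal(nrow(calls), 2)
  expect_true(all(calls$ratio > 0))
  expect_true(calls$significant[2])
})
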