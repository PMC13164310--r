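test_that("band adjacency contains exactly the within-bandwidth pairs", {
  a <- generate_adjacency(5, "band", bandwidth = 1)
  expected <- matrix(0L, 5, 5)
  for (i in 1:4) expected[i, i + 1] <- expected[i + 1, i] <- 1L
  expect_identical(a, expected)
  a2 <- generate_adjacency(6, "band", bandwidth = 2)
  expect_equal(sum(a2) / 2, 5 + 4)   # |i-j| = 1 and 2 diagonals
})

test_that("hub topology with one group is a star", {
  a <- generate_adjacency(10, "hub", n_hubs = 1)
  deg <- rowSums(a)
  expect_equal(sort(deg, decreasing = TRUE), c(9, rep(1, 9)))
})

test_that("scale-free graphs are connected with right-skewed degrees", {
  for (seed in 1:5) {
    a <- generate_adjacency(10, "scale_free", seed = seed)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_true(igraph::is_connected(g))
    expect_gte(sum(a) / 2, 9)
    deg <- rowSums(a)
    # preferential attachment: max degree well above the median degree
    expect_gt(max(deg), stats::median(deg))
  }
})

test_that("cluster topology has no between-block edges", {
  a <- generate_adjacency(10, "cluster", seed = 3, n_clusters = 2)
  blocks <- split(1:10, rep(1:2, length.out = 10))
  expect_equal(sum(a[blocks[[1]], blocks[[2]]]), 0)
})

test_that("generated adjacencies are symmetric, binary, hollow and reproducible", {
  for (topo in c("random", "scale_free", "hub", "cluster", "band")) {
    a <- generate_adjacency(12, topo, seed = 7)
    expect_identical(a, t(a))
    expect_true(all(a %in% c(0L, 1L)))
    expect_true(all(diag(a) == 0))
    expect_identical(a, generate_adjacency(12, topo, seed = 7))
  }
  expect_error(generate_adjacency(2, "band"), "at least|>= 3|must")
})

test_that("adjacency_to_precision is PD with support equal to the adjacency", {
  for (topo in c("random", "scale_free", "hub", "cluster", "band")) {
    a <- generate_adjacency(10, topo, seed = 11)
    om <- adjacency_to_precision(a)
    expect_true(is_positive_definite(om))
    expect_identical(precision_support(om), unname(a))
    expect_true(all(diag(unclass(om)) > 0))
  }
})

test_that("zero adjacency with unit jitter gives the identity scale", {
  om <- adjacency_to_precision(matrix(0, 4, 4), diag_jitter = 1)
  ev <- eigen(unclass(om), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 1, tolerance = 1e-12)
  expect_equal(structure(unclass(om), topology = NULL), diag(4))
})

test_that("3-gene chain precision has a nonzero marginal (1,3) dependence", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  om <- adjacency_to_precision(a, edge_weight = 0.5)
  sigma <- solve(unclass(om))
  # conditional independence of (1,3) given 2, but marginal dependence
  expect_equal(unclass(om)[1, 3], 0)
  expect_gt(abs(sigma[1, 3]), 1e-6)
})

test_that("degrade_edges removes the right number of edges, never adds", {
  om <- adjacency_to_precision(generate_adjacency(10, "band"))
  e0 <- sum(precision_support(om)) / 2    # 9 edges
  d <- degrade_edges(om, 0.5, seed = 1)
  # exactly round(fraction * E) edges are removed
  expect_equal(sum(precision_support(d)) / 2, e0 - round(0.5 * e0))
  expect_true(all(precision_support(d) <= precision_support(om)))
  expect_true(is_positive_definite(d))
  # determinism
  d2 <- degrade_edges(om, 0.5, seed = 1)
  expect_identical(precision_support(d), precision_support(d2))
  # 2-edge graph, fraction 0.5 -> 1 edge
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1
  om2 <- adjacency_to_precision(a)
  expect_equal(sum(precision_support(degrade_edges(om2, 0.5, seed = 2))) / 2, 1)
  expect_error(degrade_edges(om, 0), "fraction")
  expect_error(degrade_edges(om, 1.2), "fraction")
})
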