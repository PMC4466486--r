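test_that("fixed-density thresholding keeps exactly round(k * n(n-1)/2) links", {
  set.seed(91)
  a <- random_graph(64, p_edge = 1)
  net <- threshold_fixed_density(a, 0.8)
  expect_equal(net$kept_links, 1613)           # round(0.8 * 2016)
  expect_equal(sum(net$a[upper.tri(net$a)] > 0), 1613)
  expect_equal(net$a, t(net$a))
  # k = 1 keeps the matrix unchanged
  expect_equal(threshold_fixed_density(a, 1)$a, a)
  # the kept-link pattern is rank-invariant under positive scaling
  n1 <- threshold_fixed_density(a, 0.4)
  n2 <- threshold_fixed_density(a * 0.37, 0.4)
  expect_equal(n1$a > 0, n2$a > 0)
  expect_error(threshold_fixed_density(a, 0), "k_density")
  expect_error(threshold_fixed_density(a, 1.2), "k_density")
  expect_error(threshold_fixed_density(a + stats::rnorm(64 * 64) * 1e-3,
                                       0.5), "symmetric")
})

test_that("strength matches hand values and the brute-force oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  s <- strength(tri)
  expect_equal(unname(s$node), c(2, 2, 2))
  expect_equal(s$global, 2)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 0.5
  st <- strength(star)
  expect_equal(unname(st$node), c(1.5, 0.5, 0.5, 0.5))
  set.seed(92)
  for (r in 1:20) {
    a <- random_graph(8)
    expect_equal(unname(strength(a)$node), oracle_strength(a))
  }
})

test_that("weighted clustering matches hand values and the oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(clustering_coef(tri)$node), c(1, 1, 1))
  # path graph: endpoints have degree 1 hence C_i = 0
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(unname(clustering_coef(path)$node), c(0, 0, 0))
  # half-weight triangle: geometric mean of 0.5s
  htri <- tri * 0.5
  expect_equal(unname(clustering_coef(htri)$node), rep(0.5, 3))
  set.seed(93)
  for (r in 1:20) {
    a <- random_graph(8)
    expect_equal(unname(clustering_coef(a)$node), oracle_clustering(a),
                 tolerance = 1e-12)
  }
  expect_error(clustering_coef(tri * 2), "in \\[0, 1\\]")
})

test_that("local efficiency matches hand values and the Floyd-Warshall oracle", {
  comp4 <- matrix(1, 4, 4); diag(comp4) <- 0
  expect_equal(unname(local_efficiency(comp4)$node), rep(1, 4))
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  le <- local_efficiency(star)
  expect_equal(unname(le$node[1]), 0)   # leaves are mutually unreachable
  expect_equal(unname(le$node[2:4]), rep(0, 3))  # single neighbour
  set.seed(94)
  for (r in 1:20) {
    a <- random_graph(8)
    expect_equal(unname(local_efficiency(a)$node),
                 oracle_local_efficiency(a), tolerance = 1e-12)
  }
})

test_that("all measures agree with oracles on small grid-weighted graphs", {
  set.seed(95)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (n in 3:6) {
    for (r in 1:25) {
      a <- random_graph(n, p_edge = 0.7, grid = grid)
      expect_equal(unname(strength(a)$node), oracle_strength(a))
      expect_equal(unname(clustering_coef(a)$node), oracle_clustering(a),
                   tolerance = 1e-12)
      expect_equal(unname(local_efficiency(a)$node),
                   oracle_local_efficiency(a), tolerance = 1e-12)
    }
  }
})

test_that("global metrics are exact means of node metrics", {
  set.seed(96)
  a <- random_graph(10)
  net <- threshold_fixed_density(a, 0.6)
  m <- network_metrics(net)
  expect_equal(m$global$S, mean(m$node$S_i))
  expect_equal(m$global$C, mean(m$node$C_i))
  expect_equal(m$global$E, mean(m$node$E_i))
})

test_that("strength is monotone in density and metrics are permutation-equivariant", {
  set.seed(97)
  a <- random_graph(12, p_edge = 1)
  s_by_k <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(k) {
    strength(threshold_fixed_density(a, k))$global
  }, numeric(1))
  expect_true(all(diff(s_by_k) >= 0))

  perm <- sample(12)
  ap <- a[perm, perm]
  for (k in c(0.5, 1)) {
    m <- network_metrics(threshold_fixed_density(a, k))
    mp <- network_metrics(threshold_fixed_density(ap, k))
    expect_equal(mp$node$S_i, m$node$S_i[perm], tolerance = 1e-12)
    expect_equal(mp$node$C_i, m$node$C_i[perm], tolerance = 1e-12)
    expect_equal(mp$node$E_i, m$node$E_i[perm], tolerance = 1e-12)
    expect_equal(mp$global$S, m$global$S)
  }
})

test_that("density ties break deterministically", {
  a <- matrix(0.5, 4, 4); diag(a) <- 0
  n1 <- threshold_fixed_density(a, 0.5)
  n2 <- threshold_fixed_density(a, 0.5)
  expect_identical(n1$a, n2$a)
  expect_equal(sum(n1$a[upper.tri(n1$a)] > 0), 3)  # round(0.5 * 6)
  # lexicographically first pairs survive
  expect_true(n1$a[1, 2] > 0 && n1$a[1, 3] > 0 && n1$a[1, 4] > 0)
})
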