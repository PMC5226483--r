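test_that("shortest path length is the reciprocal weight on a single edge", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.5
  L <- shortest_paths_matrix(toy_network(W))
  expect_equal(L[1, 2], 2)
  expect_equal(diag(L), c(0, 0), ignore_attr = TRUE)
})

test_that("unit-weight complete graph has unit path lengths and efficiencies", {
  net <- toy_network(unit_complete(4))
  L <- shortest_paths_matrix(net)
  expect_true(all(L[upper.tri(L)] == 1))
  expect_equal(global_efficiency(L), 1)
  expect_equal(characteristic_path_length(L), 1)
  expect_equal(clustering_coefficient(net), 1)
  expect_equal(local_efficiency(net), 1) # each neighbor subgraph is unit K3
})

test_that("triangle and path clustering are the textbook values", {
  tri <- matrix(0, 3, 3); tri[cbind(c(1, 2, 1), c(2, 3, 3))] <- 1
  tri <- tri + t(tri)
  expect_equal(clustering_coefficient(toy_network(tri)), 1)
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(clustering_coefficient(toy_network(path)), 0)
})

test_that("star betweenness is (N-1)(N-2)/2 at the center and 0 at leaves", {
  n <- 5
  W <- matrix(0, n, n); W[1, 2:n] <- W[2:n, 1] <- 1
  b <- betweenness_centrality(toy_network(W))
  expect_equal(b$betweenness[1], 6) # 4*3/2
  expect_true(all(b$betweenness[-1] == 0))
  expect_equal(b$degree, c(4L, rep(1L, 4)))
  # 3-node path: middle carries the single pair
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  expect_equal(betweenness_centrality(toy_network(P))$betweenness, c(0, 1, 0))
})

test_that("local efficiency of a star is zero", {
  W <- matrix(0, 6, 6); W[1, 2:6] <- W[2:6, 1] <- 1
  expect_equal(local_efficiency(toy_network(W)), 0)
})

test_that("edgeless graph has zero efficiency and infinite Lp with warning", {
  net <- toy_network(matrix(0, 4, 4))
  L <- shortest_paths_matrix(net)
  expect_equal(global_efficiency(L), 0)
  expect_warning(lp <- characteristic_path_length(L), "disconnected|no finite")
  expect_identical(lp, Inf)
})

test_that("metrics match brute-force oracles on random toy graphs", {
  for (seed in 1:25) {
    n <- sample(5:8, 1)
    W <- random_weights(n, p = 0.5, seed = seed)
    net <- toy_network(W)
    L <- shortest_paths_matrix(net)
    expect_equal(L, oracle_floyd_warshall(W), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(betweenness_centrality(net)$betweenness, oracle_betweenness(W),
                 tolerance = 1e-10)
    expect_equal(clustering_coefficient(net), oracle_clustering(W),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(L), oracle_global_eff(W), tolerance = 1e-12)
    expect_equal(local_efficiency(net), oracle_local_eff(W), tolerance = 1e-12)
  }
})

test_that("Lp * Eg = 1 identically on networks with a finite pair", {
  for (seed in 1:10) {
    W <- random_weights(sample(6:12, 1), p = 0.4, seed = 100 + seed)
    if (sum(W) == 0) next
    L <- shortest_paths_matrix(toy_network(W))
    eg <- global_efficiency(L)
    if (eg == 0) next
    expect_equal(characteristic_path_length(L) * eg, 1, tolerance = 1e-10)
  }
})

test_that("metrics are invariant under node permutation", {
  W <- random_weights(8, p = 0.5, seed = 42)
  net <- toy_network(W)
  perm <- withr::with_seed(9, sample(8))
  Wp <- W[perm, perm]
  netp <- toy_network(Wp)
  expect_equal(clustering_coefficient(netp), clustering_coefficient(net))
  expect_equal(global_efficiency(netp), global_efficiency(net), tolerance = 1e-12)
  expect_equal(local_efficiency(netp), local_efficiency(net), tolerance = 1e-12)
  b <- betweenness_centrality(net)$betweenness
  bp <- betweenness_centrality(netp)$betweenness
  expect_equal(bp, b[perm], tolerance = 1e-10)
})

test_that("scaling all weights by c rescales Lp and Eg but not topology metrics", {
  W <- random_weights(8, p = 0.5, seed = 5)
  c0 <- 3.7
  net <- toy_network(W); net2 <- toy_network(W * c0)
  L1 <- shortest_paths_matrix(net); L2 <- shortest_paths_matrix(net2)
  expect_equal(characteristic_path_length(L2),
               characteristic_path_length(L1) / c0, tolerance = 1e-12)
  expect_equal(global_efficiency(L2), global_efficiency(L1) * c0,
               tolerance = 1e-12)
  expect_equal(local_efficiency(net2), local_efficiency(net) * c0,
               tolerance = 1e-12)
  expect_equal(clustering_coefficient(net2), clustering_coefficient(net))
  expect_equal(betweenness_centrality(net2)$betweenness,
               betweenness_centrality(net)$betweenness, tolerance = 1e-10)
})

test_that("adding an edge never lengthens a path nor lowers global efficiency", {
  W <- random_weights(8, p = 0.35, seed = 11)
  L1 <- shortest_paths_matrix(toy_network(W))
  absent <- which(upper.tri(W) & W == 0)
  expect_gt(length(absent), 0)
  W2 <- W
  W2[absent[1]] <- 1.5
  W2 <- pmax(W2, t(W2))
  L2 <- shortest_paths_matrix(toy_network(W2))
  expect_true(all(L2 <= L1 + 1e-12))
  expect_gte(global_efficiency(L2), global_efficiency(L1) - 1e-12)
})

test_that("weighted clustering variant stays in [0,1] and matches binary on unit weights", {
  net <- toy_network(unit_complete(5))
  expect_equal(clustering_coefficient(net, weighted = TRUE),
               clustering_coefficient(net))
  W <- random_weights(8, p = 0.6, seed = 2)
  cw <- clustering_coefficient(toy_network(W), weighted = TRUE)
  expect_gte(cw, 0); expect_lte(cw, 1)
})

test_that("normalized betweenness divides by the pair count", {
  W <- matrix(0, 5, 5); W[1, 2:5] <- W[2:5, 1] <- 1
  b <- betweenness_centrality(toy_network(W), normalized = TRUE)
  expect_equal(b$betweenness[1], 1) # star center lies on every pair
})
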