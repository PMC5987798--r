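test_that("strength sums incident weights and ignores self-connections", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 2
  W[2, 3] <- W[3, 2] <- 1
  expect_equal(node_strength(W), c(2, 3, 1))
  expect_equal(node_strength(matrix(0, 4, 4)), rep(0, 4))
  Wd <- W
  diag(Wd) <- c(5, 0, 0)
  expect_equal(node_strength(Wd), c(2, 3, 1))
})

test_that("shortest paths use edge length 1/w and route around weak edges", {
  W2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(shortest_path_lengths(W2)[1, 2], 2)
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 1
  W3[2, 3] <- W3[3, 2] <- 1
  W3[1, 3] <- W3[3, 1] <- 0.25
  d <- shortest_path_lengths(W3)
  expect_equal(d[1, 3], 2) # via the middle node, not the direct length-4 edge
  d0 <- shortest_path_lengths(matrix(0, 3, 3))
  expect_true(all(is.infinite(d0[upper.tri(d0)])))
  expect_true(all(diag(d0) == 0))
})

test_that("betweenness matches forced cases: star centre and complete graph", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1
  star <- star + t(star)
  bc <- betweenness_centrality(star)
  expect_equal(bc$node, c(3, 0, 0, 0))
  complete <- matrix(1, 5, 5)
  expect_equal(betweenness_centrality(complete)$node, rep(0, 5))
})

test_that("clustering matches forced cases: triangles and paths", {
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  expect_equal(clustering_coefficient(tri), rep(1, 3))
  path <- matrix(0, 4, 4)
  path[cbind(1:3, 2:4)] <- 1
  path <- path + t(path)
  expect_equal(clustering_coefficient(path), rep(0, 4))
  # geometric-mean intensity: (1 * 1 * 0.125)^(1/3) = 0.5 at every corner
  tri2 <- matrix(c(0, 1, 1, 1, 0, 0.125, 1, 0.125, 0), 3)
  expect_equal(clustering_coefficient(tri2), rep(0.5, 3))
})

test_that("global efficiency matches closed forms", {
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  expect_equal(global_efficiency(matrix(c(0, 0.5, 0.5, 0), 2)), 0.5)
  expect_error(global_efficiency(matrix(0, 1, 1)), "at least 2")
})

test_that("communicability matches closed forms", {
  expect_equal(communicability(matrix(0, 3, 3)), rep(1, 3))
  # normalised 2-node adjacency is [[0,1],[1,0]] for any positive weight:
  # row sums of its exponential are cosh(1) + sinh(1) = e
  expect_equal(communicability(matrix(c(0, 7, 7, 0), 2)), rep(exp(1), 2),
               tolerance = 1e-12)
  set.seed(41)
  W <- random_weight_matrix(3)
  expect_equal(communicability(W), bf_communicability(W), tolerance = 1e-10)
})

test_that("path, triangle and walk measures agree with brute-force oracles
           on random small graphs", {
  set.seed(20240601)
  for (trial in 1:60) {
    R <- sample(3:7, 1)
    W <- random_weight_matrix(R, p_edge = runif(1, 0.3, 0.9))
    d <- shortest_path_lengths(W)
    expect_equal(d, bf_distances(W), tolerance = 1e-9)
    expect_equal(global_efficiency(W), bf_global_efficiency(W),
                 tolerance = 1e-9)
    bc <- betweenness_centrality(W)
    oracle <- bf_betweenness(W)
    expect_equal(bc$node, oracle$node, tolerance = 1e-7)
    expect_equal(unname(bc$edge), oracle$edge, tolerance = 1e-7)
    cl <- clustering_coefficient(W)
    expect_equal(cl, bf_onnela_clustering(W), tolerance = 1e-9)
    expect_true(all(cl >= 0 & cl <= 1 + 1e-12))
    co <- communicability(W)
    expect_equal(co, bf_communicability(W), tolerance = 1e-8)
    isolated <- rowSums(W) == 0
    expect_true(all(co >= 1 - 1e-12))
    expect_equal(co[isolated], rep(1, sum(isolated)))
    expect_true(all(co[!isolated] > 1))
  }
})

test_that("all measures are invariant under simultaneous row/column permutation", {
  set.seed(77)
  for (trial in 1:10) {
    R <- sample(4:7, 1)
    W <- random_weight_matrix(R)
    p <- sample(R)
    Wp <- W[p, p]
    expect_equal(node_strength(Wp), node_strength(W)[p])
    expect_equal(betweenness_centrality(Wp)$node,
                 betweenness_centrality(W)$node[p], tolerance = 1e-9)
    expect_equal(clustering_coefficient(Wp), clustering_coefficient(W)[p])
    expect_equal(communicability(Wp), communicability(W)[p],
                 tolerance = 1e-9)
    expect_equal(global_efficiency(Wp), global_efficiency(W))
  }
})

test_that("change metrics apply the ratio rule to strength and connections
           and the difference rule to the rest", {
  # region strength dropping from 10 pre to 2 post gives change 0.2
  pre <- connectivity_matrix(matrix(c(0, 10, 10, 0), 2), 1:2)
  post <- connectivity_matrix(matrix(c(0, 2, 2, 0), 2), 1:2)
  ch <- change_metrics(pre, post)
  expect_equal(unname(ch$strength_ratio), c(0.2, 0.2))
  expect_equal(ch$connection_ratio[1, 2], 0.2)

  set.seed(51)
  W <- random_weight_matrix(5)
  W <- round(W * 10)
  cm <- connectivity_matrix(W, 1:5)
  same <- change_metrics(cm, cm, volume_remaining = rep(1, 5))
  expect_true(all(same$connection_ratio == 1))
  expect_true(all(same$strength_ratio == 1))
  expect_true(all(same$betweenness_diff == 0))
  expect_true(all(same$edge_betweenness_diff == 0))
  expect_true(all(same$clustering_diff == 0))
  expect_equal(same$communicability_diff, rep(0, 5))
  expect_equal(unname(same$efficiency["ratio"]), 1)

  # absent connections (0 pre and post) have ratio 1 by convention
  expect_true(all(same$connection_ratio[W == 0 & upper.tri(W)] == 1))
})

test_that("change metrics demand matching region sets and count weights", {
  pre <- connectivity_matrix(matrix(c(0, 3, 3, 0), 2), 1:2)
  post_other <- connectivity_matrix(matrix(c(0, 1, 1, 0), 2), 3:4)
  expect_error(change_metrics(pre, post_other), "region sets")
  expect_error(change_metrics(log_transform(pre), log_transform(pre)),
               "count")
})

test_that("tidy long format covers every metric family once per unit", {
  pre <- connectivity_matrix(matrix(c(0, 4, 2, 4, 0, 0, 2, 0, 0), 3), 1:3)
  post <- connectivity_matrix(matrix(c(0, 2, 2, 2, 0, 0, 2, 0, 0), 3), 1:3)
  df <- as.data.frame(change_metrics(pre, post,
                                     volume_remaining = c(0.5, 1, 1)))
  counts <- table(df$metric)
  expect_equal(unname(counts[["connection_strength_ratio"]]), 3)
  expect_equal(unname(counts[["region_strength_ratio"]]), 3)
  expect_equal(unname(counts[["edge_betweenness_diff"]]), 3)
  expect_equal(unname(counts[["global_efficiency"]]), 1)
  expect_equal(unname(counts[["region_volume_ratio"]]), 3)
})
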