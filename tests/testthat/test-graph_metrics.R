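triangle <- function() {
  w <- matrix(1, 3, 3); diag(w) <- 0; w
}
star4 <- function() {
  w <- matrix(0, 4, 4); w[1, 2:4] <- w[2:4, 1] <- 1; w
}

test_that("strength and mean degree on closed-form graphs", {
  expect_equal(node_strength(matrix(0, 3, 3)), c(0, 0, 0))
  expect_equal(node_strength(triangle()), c(2, 2, 2))
  expect_equal(mean_degree(triangle()), 2)
  expect_equal(mean_degree(star4()), 1.5)
})

test_that("transitivity: closed triangle is 1, star is 0", {
  expect_equal(transitivity_w(triangle()), 1)
  expect_equal(transitivity_w(star4()), 0)
  expect_equal(transitivity_w(matrix(0, 2, 2)), 0)
})

test_that("global and local efficiency on closed-form graphs", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(global_efficiency(k5), 1)
  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
  expect_equal(global_efficiency(matrix(0, 1, 1)), 0)
  expect_equal(local_efficiency(triangle()), c(1, 1, 1))
  expect_equal(local_efficiency(star4()), c(0, 0, 0, 0))
})

test_that("participation coefficient follows its defining formula", {
  # all weight inside own community
  w <- triangle()
  expect_equal(participation_coefficient(w, c(1, 1, 1)), c(0, 0, 0))
  # node 1 split equally across two communities
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 1; w2[1, 3] <- w2[3, 1] <- 1
  expect_equal(participation_coefficient(w2, c(1, 1, 2))[1], 0.5)
  # zero-strength node maps to 0
  w3 <- rbind(cbind(triangle(), 0), 0)
  expect_equal(participation_coefficient(w3, c(1, 1, 2, 2))[4], 0)
})

test_that("eigenvector centrality matches structure and dense eigensolver", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(eigenvector_centrality(k4), rep(0.5, 4))
  ec <- eigenvector_centrality(star4())
  expect_gt(ec[1], max(ec[2:4]))
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "no edges")
  set.seed(5)
  for (r in 1:20) {
    w <- random_weighted_graph(5 + r %% 3)
    if (max(w) == 0) next
    expect_equal(eigenvector_centrality(w), oracle_eigencentrality(w),
                 tolerance = 1e-9)
  }
})

test_that("modularity: partition is deterministic and Q matches the formula", {
  # two disconnected triangles: Louvain separates them and Q attains the
  # exhaustive-search maximum over all partitions of 6 nodes
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- triangle(); w[4:6, 4:6] <- triangle()
  lv <- modularity_louvain(w, seed = 3)
  expect_equal(length(unique(lv$membership)), 2)
  expect_equal(length(unique(lv$membership[1:3])), 1)
  best <- max(vapply(all_partitions(6), function(m) oracle_modularity_q(w, m),
                     numeric(1)))
  expect_equal(lv$q, best, tolerance = 1e-12)
  # K4 single community has Q = 0
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(modularity_q(k4, rep(1, 4)), 0)
  # returned Q always re-derivable from returned partition
  set.seed(9)
  w8 <- random_weighted_graph(8)
  lv8 <- modularity_louvain(w8, seed = 42)
  expect_equal(lv8$q, oracle_modularity_q(w8, lv8$membership))
  expect_identical(modularity_louvain(w8, seed = 42)$membership,
                   lv8$membership)
  expect_error(modularity_louvain(matrix(0, 4, 4)), "empty network")
})

test_that("permutation equivariance of nodal metrics, invariance of globals", {
  set.seed(21)
  w <- random_weighted_graph(7)
  perm <- sample(7)
  wp <- w[perm, perm]
  expect_equal(node_strength(wp), node_strength(w)[perm])
  expect_equal(local_efficiency(wp), local_efficiency(w)[perm])
  expect_equal(eigenvector_centrality(wp),
               eigenvector_centrality(w)[perm], tolerance = 1e-9)
  expect_equal(transitivity_w(wp), transitivity_w(w))
  expect_equal(global_efficiency(wp), global_efficiency(w))
  memb <- c(1, 1, 2, 2, 3, 3, 1)
  expect_equal(participation_coefficient(wp, memb[perm]),
               participation_coefficient(w, memb)[perm])
  expect_equal(modularity_q(wp, memb[perm]), modularity_q(w, memb))
})

test_that("weight-scale invariance: strengths scale, ratios do not", {
  set.seed(31)
  w <- random_weighted_graph(6)
  k <- 3.7
  expect_equal(node_strength(k * w), k * node_strength(w))
  expect_equal(transitivity_w(k * w), transitivity_w(w))
  memb <- c(1, 2, 1, 2, 1, 2)
  expect_equal(participation_coefficient(k * w, memb),
               participation_coefficient(w, memb))
  expect_equal(eigenvector_centrality(k * w), eigenvector_centrality(w),
               tolerance = 1e-10)
})

test_that("global_metrics composes the individually tested pieces", {
  tri <- triangle()
  gm <- global_metrics(tri, seed = 1)
  expect_equal(gm$mean_degree, 2)
  expect_equal(gm$transitivity, 1)
  expect_equal(gm$global_efficiency, 1)
  expect_error(global_metrics(matrix(0, 4, 4)), "empty network")
  set.seed(77)
  w <- random_weighted_graph(7)
  gm2 <- global_metrics(w, seed = 5)
  lv <- modularity_louvain(w, seed = 5)
  a <- normalize_adjacency(w)
  expect_equal(gm2$mean_degree, mean_degree(w))
  expect_equal(gm2$modularity_q, lv$q)
  expect_equal(gm2$mean_average_controllability,
               mean(average_controllability(a)))
  nt <- nodal_metrics(connectome(w), seed = 5)
  expect_equal(nt$strength, node_strength(w))
  expect_equal(nt$modal_controllability, modal_controllability(a))
})
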