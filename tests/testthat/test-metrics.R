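star_net <- function(n = 5) {
  m <- matrix(0, n, n)
  m[1, 2:n] <- 1; m[2:n, 1] <- 1
  new_network(m, paste0("v", 1:n), edge_kind = "binary")
}

clique_net <- function(n = 4) {
  m <- matrix(1, n, n); diag(m) <- 0
  new_network(m, paste0("v", 1:n), edge_kind = "binary")
}

test_that("degree and strength follow closed forms and coincide on 0/1 nets", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.3
  net <- new_network(m, letters[1:3])
  expect_equal(unname(node_strength(net)), c(0.8, 0.5, 0.3))
  expect_equal(unname(node_degree(net)), c(2, 1, 1))
  cl <- clique_net(4)
  expect_equal(node_degree(cl), node_strength(cl))
  expect_equal(unname(node_degree(cl)), rep(3, 4))
  iso <- new_network(matrix(0, 2, 2), c("a", "b"))
  expect_equal(unname(node_strength(iso)), c(0, 0))
  expect_error(node_degree(iso, "in"), "undirected")
})

test_that("betweenness: star centre carries all shortest paths", {
  st <- star_net(5)
  b <- node_betweenness(st)
  expect_equal(unname(b), c(choose(4, 2), 0, 0, 0, 0))
  expect_true(all(node_betweenness(clique_net(5)) == 0))
})

test_that("a bridge node has maximal betweenness but minimal degree", {
  # two 4-cliques joined through one extra node
  n <- 9
  m <- matrix(0, n, n)
  m[1:4, 1:4] <- 1; m[5:8, 5:8] <- 1; diag(m) <- 0
  m[9, c(1, 5)] <- 1; m[c(1, 5), 9] <- 1
  net <- new_network(m, paste0("v", 1:n), edge_kind = "binary")
  b <- node_betweenness(net)
  d <- node_degree(net)
  expect_equal(unname(which.max(b)), 9L)
  expect_equal(unname(d[9]), min(d))
})

test_that("eigenvector centrality: symmetry and the star closed form", {
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  rn <- new_network(ring, paste0("v", 1:6), edge_kind = "binary")
  expect_equal(unname(node_eigenvector(rn)), rep(1, 6))
  ev <- node_eigenvector(star_net(5))
  expect_equal(unname(ev), c(1, rep(1 / sqrt(4), 4)), tolerance = 1e-9)
})

test_that("pagerank sums to one; ring pagerank is uniform", {
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  rn <- new_network(ring, paste0("v", 1:6), edge_kind = "binary")
  pr <- node_pagerank(rn)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_equal(unname(pr), rep(1 / 6, 6), tolerance = 1e-9)
  expect_error(node_pagerank(rn, damping = 1.5), "damping")
})

test_that("spectral centralities rank-correlate with degree on binary toys", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- rbinom(choose(n, 2), 1, 0.5)
    a <- a + t(a)
    if (any(colSums(a) == 0) || sd(colSums(a)) == 0) next
    net <- new_network(a, paste0("v", 1:n), edge_kind = "binary")
    d <- node_degree(net)
    rho_ev <- cor(rank(suppressWarnings(node_eigenvector(net))), rank(d))
    rho_pr <- cor(rank(node_pagerank(net)), rank(d))
    expect_gt(rho_ev, 0.5)
    expect_gt(rho_pr, 0.5)
  }
})

test_that("reach counts n-step neighbourhoods and is monotone in steps", {
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  pn <- new_network(path, c("a", "b", "c"), edge_kind = "binary")
  expect_equal(unname(node_reach(pn, 1)), c(0.5, 1, 0.5))
  expect_equal(unname(node_reach(pn, 2)), c(1, 1, 1))
  expect_true(all(node_reach(clique_net(5), 1) == 1))
  net <- random_symmetric_net(8)
  r1 <- node_reach(net, 1); r2 <- node_reach(net, 2); r3 <- node_reach(net, 3)
  expect_true(all(r2 >= r1) && all(r3 >= r2))
})

test_that("density follows the dyad-count formulas", {
  expect_equal(graph_density(clique_net(5), weighted = FALSE), 1)
  expect_equal(graph_density(new_network(matrix(0, 4, 4), letters[1:4])), 0)
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- m[1, 3] <- m[3, 1] <- m[3, 4] <- m[4, 3] <- 0.5
  expect_equal(graph_density(new_network(m, letters[1:4])), 1.5 / 6)
  expect_error(graph_density(new_network(matrix(0, 1, 1), "a")), "at least 2")
})

test_that("assortativity hits the perfect-assortment extremes", {
  # two same-class cliques, no between edges
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 1; diag(m) <- 0
  net <- new_network(m, paste0("v", 1:6), edge_kind = "binary")
  expect_equal(assortativity_coef(net, rep(c("f", "m"), each = 3)), 1)
  # complete bipartite male-female
  b <- matrix(0, 6, 6)
  b[1:3, 4:6] <- 1; b[4:6, 1:3] <- 1
  bn <- new_network(b, paste0("v", 1:6), edge_kind = "binary")
  expect_equal(assortativity_coef(bn, rep(c("f", "m"), each = 3)), -1)
  expect_equal(assortativity_coef(bn, rep(c(0, 1), each = 3)), -1)
  expect_error(assortativity_coef(bn, rep(1, 6)), "constant")
})

test_that("numeric assortativity matches the weighted edge-list oracle", {
  for (seed in 1:6) {
    net <- random_symmetric_net(seed, n = 7, density = 0.7)
    set.seed(seed + 100)
    vals <- rnorm(7)
    expect_equal(assortativity_coef(net, vals),
                 oracle_assortativity(net$weights, vals), info = seed)
  }
})

test_that("binary assortativity agrees with igraph on categorical classes", {
  for (seed in 1:4) {
    net <- random_symmetric_net(seed, n = 8, density = 0.6)
    net$weights <- (net$weights > 0) + 0
    set.seed(seed)
    cls <- sample(c("x", "y"), 8, TRUE)
    if (length(unique(cls)) < 2) next
    g <- igraph::graph_from_adjacency_matrix(net$weights, "undirected")
    expect_equal(assortativity_coef(net, cls),
                 igraph::assortativity_nominal(g, factor(cls)),
                 tolerance = 1e-10, info = seed)
  }
})

test_that("transitivity: triangle 1, path 0, square 0; literal variant exposed", {
  tri <- clique_net(3)
  expect_equal(transitivity_coef(tri), 1)
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(transitivity_coef(new_network(path, letters[1:3], edge_kind = "binary")), 0)
  sq <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; sq[i, j] <- sq[j, i] <- 1 }
  expect_equal(transitivity_coef(new_network(sq, letters[1:4], edge_kind = "binary")), 0)
  expect_error(transitivity_coef(new_network(matrix(0, 3, 3), letters[1:3])), "triples")
  # literal three-edge / two-edge triad ratio on the triangle has no open triads
  expect_error(transitivity_coef(tri, "literal"), "two-edge")
})

test_that("two cliques joined by one edge split into their communities", {
  m <- matrix(0, 10, 10)
  m[1:5, 1:5] <- 1; m[6:10, 6:10] <- 1; diag(m) <- 0
  m[5, 6] <- m[6, 5] <- 1
  net <- new_network(m, paste0("v", 1:10), edge_kind = "binary")
  cm <- detect_communities(net)
  expect_equal(cm$n_communities, 2)
  memb <- cm$membership$community
  expect_equal(length(unique(memb[1:5])), 1)
  expect_equal(length(unique(memb[6:10])), 1)
  expect_true(memb[1] != memb[10])
  expect_gt(cm$modularity, 0.3)
  # complete graph: no split improves modularity
  expect_equal(detect_communities(clique_net(6))$n_communities, 1)
  expect_error(detect_communities(new_network(matrix(0, 3, 3), letters[1:3])), "edges")
})

test_that("metric rank correlation matches hand-computed ranks", {
  v1 <- c(3, 1, 4, 1, 5, 9)
  expect_equal(metric_rank_correlation(v1, v1)$spearman_rho, 1)
  expect_equal(metric_rank_correlation(v1, v1)$r_squared, 1)
  expect_equal(metric_rank_correlation(v1, -v1)$spearman_rho, -1)
  v2 <- c(2, 7, 1, 8, 2, 8)
  expect_equal(metric_rank_correlation(v1, v2)$spearman_rho,
               cor(rank(v1), rank(v2)))
  expect_error(metric_rank_correlation(v1, rep(1, 6)), "constant")
})

test_that("metrics equal brute-force oracles on exhaustive small graphs", {
  # exhaustive over all connected labeled graphs on 4 nodes, sampled on 5
  graphs4 <- all_connected_graphs(4)
  expect_equal(length(graphs4), 38)
  for (a in graphs4) {
    net <- new_network(a, paste0("v", 1:4), edge_kind = "binary")
    expect_equal(unname(node_betweenness(net)), oracle_betweenness(a, FALSE))
    tr <- oracle_transitivity(a)
    if (!is.na(tr)) expect_equal(transitivity_coef(net), tr)
  }
  graphs5 <- all_connected_graphs(5)
  set.seed(1)
  for (a in graphs5[sample(length(graphs5), 60)]) {
    net <- new_network(a, paste0("v", 1:5), edge_kind = "binary")
    expect_equal(unname(node_betweenness(net)), oracle_betweenness(a, FALSE))
  }
  # weighted versions against the inverse-weight oracle
  for (seed in 1:5) {
    net <- random_symmetric_net(seed, n = 6, density = 0.7)
    expect_equal(unname(node_betweenness(net)),
                 oracle_betweenness(net$weights, TRUE), info = seed)
  }
})
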