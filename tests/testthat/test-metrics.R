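# Weighted graph metrics against brute-force oracles and algebraic identities.

complete_graph <- function(R, w = 1) {
  m <- matrix(w, R, R); diag(m) <- 0; m
}

test_that("network cost and nodal degree match their definitions", {
  expect_equal(network_cost(complete_graph(6)), 1)
  expect_equal(network_cost(matrix(0, 6, 6)), 0)
  w <- random_connectome(82, 0.4, seed = 5)
  expect_equal(network_cost(w), oracle_cost(w))

  expect_equal(nodal_degree(complete_graph(5)), rep(1, 5))
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
  expect_equal(nodal_degree(star), c(1, rep(0.25, 4)))
})

test_that("mean nodal degree equals network cost on random connectomes", {
  for (s in 1:20) {
    w <- random_connectome(sample(5:40, 1), runif(1, 0.1, 0.9), seed = s)
    expect_equal(mean(nodal_degree(w)), network_cost(w), tolerance = 1e-12)
  }
})

test_that("weighted clustering matches exhaustive triangle enumeration", {
  expect_equal(weighted_clustering(complete_graph(6))$node, rep(1, 6))
  # a tree has no triangles
  tree <- matrix(0, 5, 5)
  tree[1, 2] <- tree[2, 1] <- 0.5
  tree[2, 3] <- tree[3, 2] <- 0.8
  tree[2, 4] <- tree[4, 2] <- 0.3
  tree[4, 5] <- tree[5, 4] <- 0.9
  expect_equal(weighted_clustering(tree)$node, rep(0, 5))

  for (s in 1:30) {
    w <- random_connectome(6, runif(1, 0.3, 0.9), seed = 100 + s)
    cl <- weighted_clustering(w)
    expect_equal(cl$node, oracle_clustering(w), tolerance = 1e-10)
    expect_equal(cl$global, mean(oracle_clustering(w)), tolerance = 1e-10)
  }
})

test_that("binary clustering reduces to the triangle fraction", {
  for (s in 1:10) {
    w <- (random_connectome(7, 0.6, seed = 200 + s) > 0) * 1
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
    ref <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(weighted_clustering(w)$node, ref, tolerance = 1e-10)
  }
})

test_that("shortest paths use 1/w lengths and match exhaustive enumeration", {
  d <- shortest_paths(complete_graph(5))
  expect_equal(d[upper.tri(d)], rep(1, 10))

  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 0.5
  chain[2, 3] <- chain[3, 2] <- 0.5
  expect_equal(shortest_paths(chain)[1, 3], 4)

  for (s in 1:25) {
    w <- random_connectome(sample(4:7, 1), runif(1, 0.4, 0.9), seed = 300 + s)
    expect_equal(shortest_paths(w), oracle_distances(w), tolerance = 1e-9)
  }
})

test_that("characteristic path length averages finite distances", {
  expect_equal(as.numeric(characteristic_path_length(complete_graph(6))), 1)
  # a complete graph admits no legal swap, so surrogates equal the input
  L <- suppressWarnings(
    characteristic_path_length(complete_graph(6), normalize = TRUE,
                               n_random = 5, seed = 1))
  expect_equal(as.numeric(L), 1)  # rewiring a complete graph is a no-op
  for (s in 1:10) {
    w <- random_connected_connectome(6, 0.6, seed = 400 + s)
    d <- oracle_distances(w)
    dd <- d[upper.tri(d)]
    expect_equal(as.numeric(characteristic_path_length(w)),
                 mean(dd[is.finite(dd)]), tolerance = 1e-9)
  }
  expect_error(characteristic_path_length(matrix(0, 4, 4)), "edgeless")
})

test_that("efficiency matches the inverse-distance oracle and handles splits", {
  expect_equal(global_efficiency(complete_graph(6)), 1)
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- 1
  two[3, 4] <- two[4, 3] <- 1
  # 4 of 12 ordered pairs connected at distance 1
  expect_equal(global_efficiency(two), 4 / 12)
  for (s in 1:20) {
    w <- random_connectome(sample(4:7, 1), runif(1, 0.3, 0.9), seed = 500 + s)
    d <- oracle_distances(w)
    inv <- 1 / d; diag(inv) <- 0
    expect_equal(global_efficiency(w), mean(inv[row(inv) != col(inv)]),
                 tolerance = 1e-9)
  }
})

test_that("nodal efficiency is the efficiency of the neighbour subgraph", {
  w <- random_connectome(7, 0.7, seed = 600)
  ne <- nodal_efficiency(w)
  for (i in 1:7) {
    nb <- which(w[i, ] > 0)
    ref <- if (length(nb) < 2) 0 else global_efficiency(w[nb, nb])
    expect_equal(ne[i], ref)
  }
})

test_that("betweenness matches exhaustive shortest-path counting", {
  expect_equal(betweenness_centrality(complete_graph(5)), rep(0, 5))
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 1
  chain[2, 3] <- chain[3, 2] <- 1
  expect_equal(betweenness_centrality(chain), c(0, 1, 0))
  for (s in 1:15) {
    w <- random_connectome(sample(4:6, 1), runif(1, 0.4, 0.9), seed = 700 + s)
    expect_equal(betweenness_centrality(w), oracle_betweenness(w),
                 tolerance = 1e-9)
  }
})

test_that("random references preserve degrees, edges and weights", {
  for (s in 1:10) {
    w <- random_connected_connectome(12, 0.4, seed = 800 + s)
    wr <- random_reference(w, rewires_per_edge = 10, seed = s)
    expect_equal(rowSums(wr > 0), rowSums(w > 0))              # degree sequence
    expect_equal(sum(wr > 0), sum(w > 0))                      # edge count
    expect_equal(sort(wr[upper.tri(wr) & wr > 0]),
                 sort(w[upper.tri(w) & w > 0]))                # weight multiset
  }
})

test_that("rewiring destroys lattice clustering in almost every run", {
  R <- 20
  lat <- matrix(0, R, R)
  for (i in seq_len(R)) for (d in 1:2) {
    j <- ((i + d - 1) %% R) + 1
    lat[i, j] <- lat[j, i] <- 1
  }
  c0 <- weighted_clustering(lat)$global
  expect_gt(c0, 0.4)
  drops <- vapply(1:100, function(s) {
    weighted_clustering(random_reference(lat, 20, seed = s))$global < c0
  }, logical(1))
  expect_gte(sum(drops), 95)
})

test_that("binarization keeps the strongest edges with deterministic ties", {
  w <- random_connectome(10, 0.8, seed = 900)
  b1 <- binarize_at_cost(w, 1)
  expect_equal(b1 > 0, w > 0)
  np <- 10 * 9 / 2
  bmin <- binarize_at_cost(w, 1 / np)
  expect_equal(sum(bmin) / 2, 1)
  expect_equal(which(bmin[upper.tri(bmin)] > 0),
               which.max(w[upper.tri(w)]))
  # sort oracle at an intermediate cost
  kappa <- 0.3
  b <- binarize_at_cost(w, kappa)
  k <- round(kappa * np)
  vals <- w[upper.tri(w)]
  expect_equal(sum(b[upper.tri(b)]), k)
  expect_true(min(vals[b[upper.tri(b)] > 0]) >= max(0, sort(vals, decreasing = TRUE)[k]))
  # deterministic under ties
  wt <- matrix(0, 5, 5); wt[upper.tri(wt)] <- 0.5
  wt <- wt + t(wt)
  expect_identical(binarize_at_cost(wt, 0.3), binarize_at_cost(wt, 0.3))
  expect_error(binarize_at_cost(w, 0), "kappa")
})

test_that("cost integration averages the metric over the grid", {
  w <- random_connectome(5, 0.9, seed = 901)
  grid <- c(0.2, 0.5, 0.8)
  # direct enumeration of the three binary values
  vals <- vapply(grid, function(k) global_efficiency(binarize_at_cost(w, k)),
                 numeric(1))
  ci <- cost_integrated_metric(w, global_efficiency, grid)
  expect_equal(as.numeric(ci), mean(vals))
  # a metric constant in cost integrates to that constant
  const <- cost_integrated_metric(w, function(x) 0.7, grid)
  expect_equal(as.numeric(const), 0.7)
})

test_that("the default cost grid spans a single edge to the common maximum", {
  grid <- cost_grid(n = 50, kappa_max = 0.3538, R = 82)
  expect_equal(grid[1], 1 / 3321)
  expect_equal(grid[length(grid)], 0.3538)
  expect_true(all(diff(grid) > 0))
})

test_that("metrics are equivariant under node relabeling", {
  w <- random_connected_connectome(9, 0.5, seed = 902)
  set.seed(903)
  perm <- sample(9)
  wp <- w[perm, perm]
  expect_equal(network_cost(wp), network_cost(w))
  expect_equal(nodal_degree(wp), nodal_degree(w)[perm])
  expect_equal(weighted_clustering(wp)$node, weighted_clustering(w)$node[perm])
  expect_equal(global_efficiency(wp), global_efficiency(w))
  expect_equal(betweenness_centrality(wp), betweenness_centrality(w)[perm],
               tolerance = 1e-12)
})

test_that("removing an edge never increases cost, degree or efficiency", {
  w <- random_connected_connectome(8, 0.6, seed = 904)
  pr <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  for (k in sample(nrow(pr), 5)) {
    w2 <- w
    w2[pr[k, 1], pr[k, 2]] <- w2[pr[k, 2], pr[k, 1]] <- 0
    expect_lt(network_cost(w2), network_cost(w))
    expect_true(all(nodal_degree(w2) <= nodal_degree(w)))
    expect_lte(global_efficiency(w2), global_efficiency(w))
  }
})

test_that("stack-level helpers agree with per-subject computation", {
  set.seed(905)
  atlas <- dk_atlas()
  mats <- lapply(1:3, function(k) random_connectome(82, 0.3))
  names(mats) <- sprintf("s%d", 1:3)
  stack <- connectome_stack(mats, atlas)
  costs <- stack_costs(stack)
  degs <- stack_degrees(stack)
  for (k in 1:3) {
    w <- connectome_matrix(stack, k)
    expect_equal(unname(costs[k]), network_cost(w))
    expect_equal(unname(degs[k, ]), unname(nodal_degree(w)))
  }
  tidy_tab <- compute_metrics(stack, c("cost", "degree"))
  expect_equal(nrow(tidy_tab), 3 * (1 + 82))
  expect_equal(unname(tidy_tab$value[tidy_tab$metric == "cost"]),
               unname(costs))
})
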