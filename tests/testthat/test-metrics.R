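test_that("degree, betweenness, closeness and clustering match hand-derived values", {
  # path of three nodes
  g <- tract_graph(graph_path3)
  expect_identical(unname(degree(g)), c(1L, 2L, 1L))
  expect_equal(unname(betweenness(g)), c(0, 1, 0))
  expect_equal(unname(closeness(g, "avg_path_length")), c(1.5, 1, 1.5),
               ignore_attr = TRUE)
  expect_equal(unname(closeness(g, "inverse_avg_path")), c(2 / 3, 1, 2 / 3),
               ignore_attr = TRUE)
  expect_equal(unname(clustering_coefficient(g)), c(0, 0, 0))

  # star with four leaves: C(4,2) = 6 pairs all cross the centre
  s <- tract_graph(graph_star4)
  expect_equal(unname(betweenness(s)), c(6, 0, 0, 0, 0))
  expect_equal(unname(closeness(s, "inverse_avg_path"))[1], 1)
  expect_equal(unname(closeness(s, "avg_path_length"))[1], 1)

  # 4-cycle: for each of the two opposite pairs, two shortest paths,
  # each interior node carries 1/2
  c4 <- tract_graph(graph_cycle4)
  expect_equal(unname(betweenness(c4)), rep(0.5, 4))

  # complete graphs
  k4 <- tract_graph(1 - diag(4))
  expect_identical(unname(degree(k4)), rep(3L, 4))
  expect_equal(unname(closeness(k4, "inverse_avg_path")), rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(unname(clustering_coefficient(k4)), rep(1, 4))

  # K4 minus one edge: the two full-degree nodes have 2 of 3
  # neighbour pairs connected
  a <- 1 - diag(4)
  a[1, 2] <- a[2, 1] <- 0
  cc <- clustering_coefficient(tract_graph(a))
  expect_equal(unname(cc[3]), 2 / 3)
  expect_equal(unname(cc[4]), 2 / 3)

  # triangle clustering, single edge degenerate values
  tri <- tract_graph(1 - diag(3))
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  e <- tract_graph(rbind(c(0, 1), c(1, 0)))
  expect_identical(unname(degree(e)), c(1L, 1L))
  expect_equal(unname(betweenness(e)), c(0, 0))
  expect_equal(unname(clustering_coefficient(e)), c(0, 0))
})

test_that("metrics equal exhaustive-enumeration oracles on seeded random graphs", {
  cases <- expand.grid(n = c(5, 8, 12), p = c(0.2, 0.5, 0.8))
  reps <- 23                       # 9 x 23 > 200 graphs
  worst <- 0
  for (row in seq_len(nrow(cases))) {
    for (r in seq_len(reps)) {
      seed <- 1000 * row + r
      a <- er_graph(cases$n[row], cases$p[row], seed)
      g <- tract_graph(a)
      expect_identical(unname(degree(g)), as.integer(rowSums(a)))
      db <- max(abs(unname(betweenness(g)) - oracle_betweenness(a)))
      dcs <- abs(unname(closeness(g)) - oracle_closeness(a))
      dc <- if (all(is.na(dcs))) 0 else max(dcs, na.rm = TRUE)
      dl <- max(abs(unname(clustering_coefficient(g)) - oracle_clustering(a)))
      worst <- max(worst, db, dc, dl)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    a <- er_graph(10, 0.4, seed)
    g <- tract_graph(a)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(unname(betweenness(g)), igraph::betweenness(ig),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unname(clustering_coefficient(g)),
                 ifelse(is.nan(igraph::transitivity(ig, "local")), 0,
                        igraph::transitivity(ig, "local")),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("distance-based metrics respect components and isolated nodes", {
  # two components: a triangle and an isolated pair, plus one isolate
  a <- matrix(0, 6, 6)
  a[cbind(c(1, 1, 2, 4), c(2, 3, 3, 5))] <- 1
  a <- a + t(a)
  g <- tract_graph(a)
  comp <- graph_components(g)
  expect_identical(unname(comp), c(1L, 1L, 1L, 2L, 2L, 3L))
  cl <- closeness(g)
  expect_true(is.na(cl[6]))                       # isolated: undefined
  expect_equal(unname(attr(cl, "n_reachable")), c(2, 2, 2, 1, 1, 0))
  expect_equal(unname(betweenness(g)), rep(0, 6)) # no cross-component pairs
  rep <- centrality_report(g)
  expect_identical(rep$component, c(1L, 1L, 1L, 2L, 2L, 3L))
})

test_that("all metrics are invariant under node relabelling", {
  set.seed(42)
  for (r in 1:10) {
    a <- er_graph(9, 0.4, 500 + r)
    perm <- sample(9)
    ap <- a[perm, perm]
    for (fn in list(function(x) unname(degree(x)),
                    function(x) unname(betweenness(x)),
                    function(x) as.vector(closeness(x)),
                    function(x) unname(clustering_coefficient(x)))) {
      expect_equal(fn(tract_graph(ap)), fn(tract_graph(a))[perm])
    }
  }
})

test_that("tree betweenness equals the pair-counting identity", {
  # on a tree the unique s-t path passes v iff s and t lie in different
  # branches around v; compare against counting pairs explicitly
  set.seed(7)
  for (r in 1:5) {
    n <- 10
    # random tree: attach each node to a random earlier node
    a <- matrix(0, n, n)
    for (v in 2:n) {
      u <- sample(v - 1, 1)
      a[u, v] <- a[v, u] <- 1
    }
    d <- oracle_distances(a)
    count <- numeric(n)
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      onpath <- which(d[s, ] + d[, t] == d[s, t])
      count[setdiff(onpath, c(s, t))] <-
        count[setdiff(onpath, c(s, t))] + 1
    }
    expect_equal(unname(betweenness(tract_graph(a))), count)
    # degree-1 nodes on a tree carry no paths
    expect_true(all(betweenness(tract_graph(a))[rowSums(a) == 1] == 0))
  }
})

test_that("graph construction rejects malformed adjacency input", {
  expect_error(tract_graph(matrix(1, 2, 3)), "square")
  expect_error(tract_graph(rbind(c(0, 2), c(2, 0))), "0 or 1")
  expect_error(tract_graph(rbind(c(0, 1), c(0, 0))), "symmetric")
  expect_error(tract_graph(diag(2)), "diagonal")
  expect_error(tract_graph(graph_path3, node_names = c("a", "a", "b")),
               "unique")
})
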