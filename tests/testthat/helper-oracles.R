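# Independent oracles: exhaustive-enumeration implementations of every
# graph measure, sharing no code with the package internals.

# all-pairs shortest distances by Floyd-Warshall
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# every shortest path between two nodes, by depth-first enumeration that
# only steps to neighbours strictly closer to the target
oracle_all_shortest_paths <- function(a, s, t, d = oracle_distances(a)) {
  if (!is.finite(d[s, t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (w in which(a[v, ] == 1)) {
      if (d[w, t] == d[v, t] - 1) walk(w, c(acc, w))
    }
  }
  walk(s, s)
  paths
}

oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  cb <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_all_shortest_paths(a, s, t, d)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        cb[interior] <- cb[interior] + 1 / length(paths)
      }
    }
  }
  cb
}

oracle_closeness <- function(a, mode = "inverse_avg_path") {
  d <- oracle_distances(a)
  diag(d) <- Inf
  apply(d, 1, function(row) {
    reach <- is.finite(row)
    if (!any(reach)) return(NA_real_)
    if (mode == "inverse_avg_path") sum(reach) / sum(row[reach])
    else sum(row[reach]) / sum(reach)
  })
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1))
      for (j in (i + 1):k)
        links <- links + a[nb[i], nb[j]]
    2 * links / (k * (k - 1))
  }, 0)
}

# modularity by the direct double sum over node pairs
oracle_modularity <- function(a, memb) {
  k <- rowSums(a)
  m2 <- sum(k)
  same <- outer(memb, memb, `==`)
  sum((a - outer(k, k) / m2) * same) / m2
}

# all set partitions of n elements (restricted-growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      grow(c(prefix, lab), max(maxlab, lab))
  }
  grow(integer(0), 0L)
  out
}

# seeded Erdos-Renyi graph as plain adjacency matrix
er_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# small named example graphs used across tests
graph_path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
graph_two_triangles <- local({
  a <- matrix(0, 6, 6)
  a[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
  a + t(a)
})
graph_star4 <- local({            # centre node 1, four leaves
  a <- matrix(0, 5, 5)
  a[1, 2:5] <- 1
  a + t(a)
})
graph_cycle4 <- local({
  a <- matrix(0, 4, 4)
  a[cbind(1:4, c(2, 3, 4, 1))] <- 1
  a + t(a)
})
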