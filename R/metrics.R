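#' Node degree
#'
#' Number of edges incident to each node: the row sums of the binary
#' adjacency matrix.
#'
#' @param g A [tract_graph()] or symmetric 0/1 adjacency matrix.
#' @return Named integer vector, one entry per node.
#' @export
degree <- function(g) {
  g <- as_tract_graph(g)
  d <- rowSums(g$adjacency)
  storage.mode(d) <- "integer"
  names(d) <- g$node_names
  d
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' For each node `v`, the sum over unordered pairs of distinct other nodes
#' `(s, t)` of the fraction of shortest `s`-`t` paths that pass through `v`.
#' Path counting is fractional and endpoints are excluded; pairs in
#' different components contribute nothing. Computed with Brandes'
#' dependency accumulation, one breadth-first search per source.
#'
#' @inheritParams degree
#' @return Named numeric vector of betweenness scores.
#' @references Brandes, U. (2001) A faster algorithm for betweenness
#'   centrality. Journal of Mathematical Sociology 25, 163-177.
#' @export
betweenness <- function(g) {
  g <- as_tract_graph(g)
  adj <- adjacency_list(g)
  n <- length(adj)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(n)
    queue <- integer(n)
    queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      order_visited[head] <- v
      head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in order_visited[seq_len(tail)][tail:1L]) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  cb <- cb / 2
  names(cb) <- g$node_names
  cb
}

#' Closeness centrality and average path length
#'
#' `mode = "inverse_avg_path"` returns, for each node, the number of
#' reachable other nodes divided by the sum of shortest-path distances to
#' them (the inverse average path length); `mode = "avg_path_length"`
#' returns the average shortest-path distance itself. Nodes in other
#' components are excluded from the average; the size of the reachable set
#' is attached as attribute `n_reachable`. Isolated nodes have no defined
#' value and yield `NA`.
#'
#' @inheritParams degree
#' @param mode Either `"inverse_avg_path"` (the default) or
#'   `"avg_path_length"`.
#' @return Named numeric vector with attribute `n_reachable`.
#' @export
closeness <- function(g, mode = c("inverse_avg_path", "avg_path_length")) {
  mode <- match.arg(mode)
  g <- as_tract_graph(g)
  adj <- adjacency_list(g)
  n <- length(adj)
  out <- numeric(n)
  nreach <- integer(n)
  for (v in seq_len(n)) {
    d <- bfs_distances(adj, v)
    reach <- d > 0L
    nreach[v] <- sum(reach)
    if (nreach[v] == 0L) {
      out[v] <- NA_real_
    } else if (mode == "inverse_avg_path") {
      out[v] <- nreach[v] / sum(d[reach])
    } else {
      out[v] <- sum(d[reach]) / nreach[v]
    }
  }
  names(out) <- g$node_names
  attr(out, "n_reachable") <- stats::setNames(nreach, g$node_names)
  out
}

#' Local clustering coefficient
#'
#' Watts-Strogatz local coefficient: for a node with degree `k >= 2`, twice
#' the number of edges among its neighbours divided by `k (k - 1)`. Nodes
#' of degree 0 or 1 are assigned 0.
#'
#' @inheritParams degree
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  g <- as_tract_graph(g)
  a <- g$adjacency
  n <- nrow(a)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    out[v] <- sum(a[nb, nb]) / (k * (k - 1))
  }
  names(out) <- g$node_names
  out
}

#' Newman modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (K_c / 2m)^2 ]` where `m` is the total number of
#' edges, `e_c` the number of edges inside module `c` and `K_c` the total
#' degree of its nodes: the observed intra-module edge fraction minus its
#' expectation under a degree-preserving random rewiring.
#'
#' @inheritParams degree
#' @param membership Integer (or factor) vector assigning every node to a
#'   module.
#' @return A single numeric value in `[-0.5, 1]`.
#' @export
modularity_q <- function(g, membership) {
  g <- as_tract_graph(g)
  a <- g$adjacency
  n <- nrow(a)
  membership <- as.integer(as.factor(membership))
  if (length(membership) != n || anyNA(membership))
    stop("membership must assign every node to a module")
  m <- sum(a) / 2
  if (m == 0) stop("modularity is undefined for an edgeless graph")
  k <- rowSums(a)
  q <- 0
  for (c0 in unique(membership)) {
    idx <- membership == c0
    e_c <- sum(a[idx, idx]) / 2
    k_c <- sum(k[idx])
    q <- q + e_c / m - (k_c / (2 * m))^2
  }
  q
}

#' Per-node centrality report
#'
#' Assembles all binary-graph measures into one node-keyed table: module
#' (optional), component membership, degree, betweenness, closeness in both
#' conventions, and the local clustering coefficient.
#'
#' @inheritParams degree
#' @param partition Optional [module_partition] (or membership vector)
#'   whose assignment is included as a `module` column.
#' @return A data frame with one row per node.
#' @export
centrality_report <- function(g, partition = NULL) {
  g <- as_tract_graph(g)
  cl <- closeness(g, "inverse_avg_path")
  apl <- closeness(g, "avg_path_length")
  out <- data.frame(
    node = g$node_names,
    component = unname(graph_components(g)),
    degree = unname(degree(g)),
    betweenness = unname(betweenness(g)),
    closeness = unname(cl),
    avg_path_length = unname(apl),
    n_reachable = unname(attr(cl, "n_reachable")),
    clustering = unname(clustering_coefficient(g)),
    stringsAsFactors = FALSE
  )
  if (!is.null(partition)) {
    memb <- if (inherits(partition, "module_partition"))
      partition$membership else partition
    out <- cbind(out[, "node", drop = FALSE],
                 module = as.integer(memb),
                 out[, -1, drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
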