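#' Binary undirected graph of tract connections
#'
#' A `tract_graph` wraps a symmetric 0/1 adjacency matrix with a zero
#' diagonal and named nodes. All network measures in the package operate on
#' this representation, mirroring the binary, non-directional adjacency used
#' for group-level connectome analysis.
#'
#' @param adjacency Square numeric matrix of 0s and 1s; must be symmetric
#'   with a zero diagonal. Row/column names are used as node names when
#'   `node_names` is missing.
#' @param node_names Optional character vector of node names, one per row of
#'   `adjacency`.
#' @return An object of class `tract_graph`: a list with elements
#'   `adjacency` (integer matrix) and `node_names`.
#' @examples
#' g <- tract_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
#'                  node_names = c("a", "b", "c"))
#' degree(g)
#' @export
tract_graph <- function(adjacency, node_names = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  if (any(is.na(adjacency)) || !all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal")
  if (is.null(node_names)) node_names <- rownames(adjacency)
  if (is.null(node_names)) node_names <- paste0("V", seq_len(nrow(adjacency)))
  if (length(node_names) != nrow(adjacency))
    stop("node_names length must match the adjacency dimension")
  if (anyDuplicated(node_names))
    stop("node names must be unique")
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(node_names, node_names)
  structure(list(adjacency = adjacency, node_names = node_names),
            class = "tract_graph")
}

#' @export
print.tract_graph <- function(x, ...) {
  n <- length(x$node_names)
  m <- sum(x$adjacency) / 2
  cat(sprintf("tract_graph: %d nodes, %d edges\n", n, m))
  comp <- graph_components(x)
  cat(sprintf("components: %d (largest %d nodes)\n",
              max(comp), max(tabulate(comp))))
  invisible(x)
}

#' @export
summary.tract_graph <- function(object, ...) {
  d <- degree(object)
  cat(sprintf("tract_graph with %d nodes, %d edges\n",
              length(d), sum(d) / 2))
  cat("degree distribution:\n")
  print(summary(d))
  invisible(object)
}

# coerce matrices transparently so metric functions accept either form
as_tract_graph <- function(g) {
  if (inherits(g, "tract_graph")) return(g)
  tract_graph(g)
}

#' Read or write a graph as a delimited adjacency matrix or edge list
#'
#' Adjacency matrices are written as tab-separated text with node names as
#' header row and first column; edge lists as two-column tables of node
#' names, one undirected edge per line.
#'
#' @param g A [tract_graph()] (or adjacency matrix).
#' @param file Path to a text file.
#' @return `read_adjacency()` returns a `tract_graph`; the writers return
#'   `file` invisibly. `as_edge_list()` returns a two-column data frame.
#' @export
write_adjacency <- function(g, file) {
  g <- as_tract_graph(g)
  utils::write.table(g$adjacency, file = file, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(file)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(file) {
  m <- as.matrix(utils::read.table(file, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  tract_graph(m)
}

#' @rdname write_adjacency
#' @export
as_edge_list <- function(g) {
  g <- as_tract_graph(g)
  idx <- which(upper.tri(g$adjacency) & g$adjacency == 1, arr.ind = TRUE)
  data.frame(from = g$node_names[idx[, 1]], to = g$node_names[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' @rdname write_adjacency
#' @export
write_edge_list <- function(g, file) {
  utils::write.table(as_edge_list(g), file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_adjacency
#' @param node_names For `edge_list_graph()`, the full node set (isolated
#'   nodes are not recoverable from the edges alone).
#' @param edges Two-column matrix or data frame of node names.
#' @export
edge_list_graph <- function(edges, node_names) {
  edges <- as.matrix(edges)
  if (!all(edges %in% node_names))
    stop("edge list refers to nodes outside node_names")
  a <- matrix(0L, length(node_names), length(node_names),
              dimnames = list(node_names, node_names))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (i == j) stop("self-loops are not allowed")
    a[i, j] <- 1L
    a[j, i] <- 1L
  }
  tract_graph(a)
}

# BFS distances from one source; -1 marks unreachable
bfs_distances <- function(adj, s) {
  n <- length(adj)
  dist <- rep(-1L, n)
  dist[s] <- 0L
  queue <- s
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

adjacency_list <- function(g) {
  a <- g$adjacency
  lapply(seq_len(nrow(a)), function(i) which(a[i, ] == 1L))
}

#' Connected components of a binary graph
#'
#' @param g A [tract_graph()] or adjacency matrix.
#' @return Integer vector of component ids (1-based, labelled in order of
#'   first member), named by node.
#' @export
graph_components <- function(g) {
  g <- as_tract_graph(g)
  adj <- adjacency_list(g)
  n <- length(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    reach <- bfs_distances(adj, s)
    comp[reach >= 0L & comp == 0L] <- cur
  }
  names(comp) <- g$node_names
  comp
}
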