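#' Modularity-based module detection
#'
#' Partitions a binary graph into modules by maximizing Newman modularity
#' `Q`. Two optimizers are provided, both written for this package:
#'
#' * `"spectral"` (default): Newman's spectral bisection on the modularity
#'   matrix, recursively splitting each module along the leading
#'   eigenvector of its generalized modularity matrix, with a
#'   Kernighan-Lin style single-vertex-move refinement after every split.
#' * `"louvain"`: multi-level greedy local moves with graph aggregation.
#'
#' The best of `n_restarts` runs (by `Q`) is returned. Restarts differ in
#' the random sweep order of the refinement (and node order for Louvain),
#' so the result is deterministic given `rng_seed`. Modules are labelled by
#' decreasing size, ties broken by the smallest member index.
#'
#' @inheritParams degree
#' @param method `"spectral"` or `"louvain"`.
#' @param n_restarts Number of randomized runs to take the best of.
#' @param rng_seed Integer seed controlling all randomness.
#' @return An object of class `module_partition`: list with `membership`
#'   (named integer vector), `q`, `n_modules`, `method`, `n_restarts`,
#'   `rng_seed`.
#' @examples
#' a <- matrix(0, 6, 6)
#' a[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
#' a <- a + t(a)
#' detect_modules(a, rng_seed = 1)
#' @export
detect_modules <- function(g, method = c("spectral", "louvain"),
                           n_restarts = 20, rng_seed = 1) {
  method <- match.arg(method)
  g <- as_tract_graph(g)
  a <- g$adjacency
  if (sum(a) == 0)
    stop("module detection is undefined for an edgeless graph")
  runner <- switch(method,
                   spectral = spectral_partition,
                   louvain = louvain_partition)
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old))
  best_q <- -Inf
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    memb <- runner(a)
    q <- modularity_q(g, memb)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  memb <- relabel_by_size(best)
  names(memb) <- g$node_names
  structure(list(membership = memb, q = best_q,
                 n_modules = max(memb), method = method,
                 n_restarts = n_restarts, rng_seed = rng_seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f (%s, best of %d runs)\n",
              x$n_modules, x$q, x$method, x$n_restarts))
  for (m in seq_len(x$n_modules)) {
    members <- names(x$membership)[x$membership == m]
    cat(sprintf("  module %d (%d): %s\n", m, length(members),
                paste(members, collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.module_partition <- function(x, g = NULL, ...) {
  ord <- order(x$membership)
  if (is.null(g)) {
    graphics::plot(seq_along(x$membership), x$membership[ord],
                   xlab = "node (sorted)", ylab = "module", pch = 19, ...)
  } else {
    g <- as_tract_graph(g)
    a <- g$adjacency[ord, ord]
    graphics::image(seq_len(nrow(a)), seq_len(nrow(a)), t(a[nrow(a):1, ]),
                    col = c("white", "grey20"), axes = FALSE,
                    xlab = "", ylab = "", ...)
    graphics::box()
  }
  invisible(x)
}

# modules labelled 1..M by decreasing size; ties by smallest member index
relabel_by_size <- function(memb) {
  memb <- as.integer(as.factor(memb))
  sizes <- tabulate(memb)
  first <- vapply(seq_along(sizes), function(m) min(which(memb == m)), 0L)
  ord <- order(-sizes, first)
  out <- integer(length(memb))
  for (new in seq_along(ord)) out[memb == ord[new]] <- new
  out
}

# ---- Newman spectral bisection with KL-style refinement --------------------

spectral_partition <- function(a) {
  n <- nrow(a)
  k <- colSums(a)
  m2 <- sum(k)                       # 2m
  b <- a - outer(k, k) / m2          # modularity matrix
  ci <- rep(1L, n)
  next_id <- 1L
  queue <- 1L
  while (length(queue)) {
    c0 <- queue[1L]
    idx <- which(ci == c0)
    if (length(idx) < 2L) { queue <- queue[-1L]; next }
    bg <- b[idx, idx, drop = FALSE]
    diag(bg) <- diag(bg) - rowSums(bg)   # generalized modularity matrix
    v1 <- eigen(bg, symmetric = TRUE)$vectors[, 1L]
    s <- ifelse(v1 >= 0, 1, -1)
    tiny <- abs(v1) < 1e-12
    if (any(tiny)) s[tiny] <- sample(c(-1, 1), sum(tiny), replace = TRUE)
    s <- kl_refine(bg, s)
    q_gain <- drop(s %*% bg %*% s)
    if (q_gain <= 1e-10 || all(s == 1) || all(s == -1)) {
      queue <- queue[-1L]
      next
    }
    next_id <- next_id + 1L
    ci[idx[s == -1]] <- next_id
    queue <- c(c0, next_id, queue[-1L])
  }
  ci
}

# Kernighan-Lin style refinement of a two-way split: repeatedly sweep over
# all vertices, flipping each exactly once in greedy order, and keep the
# best configuration seen; iterate while the sweep improves s' B s.
kl_refine <- function(bg, s) {
  q <- drop(s %*% bg %*% s)
  repeat {
    s_best <- st <- s
    q_best <- qt <- q
    remaining <- sample(length(s))
    while (length(remaining)) {
      gains <- vapply(remaining,
                      function(i) qt - 4 * st[i] * sum(bg[i, ] * st) +
                        4 * bg[i, i],
                      0)
      j <- which.max(gains)
      i <- remaining[j]
      qt <- gains[j]
      st[i] <- -st[i]
      remaining <- remaining[-j]
      if (qt > q_best + 1e-12) {
        q_best <- qt
        s_best <- st
      }
    }
    if (q_best > q + 1e-12) {
      q <- q_best
      s <- s_best
    } else {
      return(s)
    }
  }
}

# ---- Louvain (multi-level greedy with aggregation) -------------------------

louvain_partition <- function(a) {
  w <- a * 1.0                 # working (possibly aggregated) weight matrix
  node_comm <- seq_len(nrow(a))  # original node -> current super-node
  m2 <- sum(w)
  repeat {
    n <- nrow(w)
    k <- rowSums(w)
    comm <- seq_len(n)
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample(n)) {
        ci <- comm[i]
        # weight from i to each community (self-weight excluded)
        wi <- w[i, ]
        wi[i] <- 0
        w_to <- tapply(wi, comm, sum)
        k_tot <- tapply(k, comm, sum)
        cand <- names(w_to)[w_to > 0]
        cand <- union(cand, as.character(ci))
        base <- w_to[as.character(ci)]
        if (is.na(base)) base <- 0
        best_gain <- 0
        best_c <- ci
        for (cc in cand) {
          c2 <- as.integer(cc)
          if (c2 == ci) next
          w_new <- w_to[cc]
          if (is.na(w_new)) w_new <- 0
          gain <- 2 * (w_new - base) / m2 -
            2 * k[i] * (k_tot[cc] - (k_tot[as.character(ci)] - k[i])) / m2^2
          if (gain > best_gain + 1e-12) {
            best_gain <- gain
            best_c <- c2
          }
        }
        if (best_c != ci) {
          comm[i] <- best_c
          moved <- TRUE
          moved_any <- TRUE
        }
      }
      if (!moved) break
    }
    comm <- as.integer(as.factor(comm))
    node_comm <- comm[node_comm]
    nc <- max(comm)
    if (!moved_any || nc == n) {
      return(as.integer(as.factor(node_comm)))
    }
    # aggregate: w'_{cd} = sum of weights between communities (diagonal
    # accumulates twice the internal weight, preserving sum(w) = 2m)
    agg <- matrix(0, nc, nc)
    for (c1 in seq_len(nc)) {
      idx1 <- comm == c1
      for (c2 in c1:nc) {
        val <- sum(w[idx1, comm == c2, drop = FALSE])
        agg[c1, c2] <- val
        agg[c2, c1] <- val
      }
    }
    w <- agg
  }
}

# seed handling: run under a private RNG stream, restoring the caller's
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
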