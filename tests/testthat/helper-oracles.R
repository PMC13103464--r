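# Brute-force oracles, independent of the package implementation: plain
# Floyd-Warshall distances, exhaustive triangle counting, and betweenness by
# explicit enumeration of all shortest paths. Only usable on small graphs.

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]] == 1) links <- links + 1
      }
    }
    nodal[i] <- 2 * links / (k * (k - 1))
  }
  list(global = mean(nodal), nodal = nodal)
}

bf_cpl <- function(adj) {
  d <- bf_distances(adj)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

bf_eglobal <- function(adj) {
  d <- bf_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(adj) * (nrow(adj) - 1))
}

bf_nodal_eff <- function(adj) {
  d <- bf_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

bf_local_eff <- function(adj) {
  vapply(seq_len(nrow(adj)), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    bf_eglobal(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

# all shortest paths between s and t, as lists of vertices, via the
# shortest-path DAG implied by brute-force distances
bf_all_shortest_paths <- function(adj, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (v in which(adj[s, ] == 1)) {
    if (d[s, t] == 1 + d[v, t]) {
      for (p in bf_all_shortest_paths(adj, d, v, t)) {
        out[[length(out) + 1]] <- c(s, p)
      }
    }
  }
  out
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- bf_all_shortest_paths(adj, d, s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        b[inner] <- b[inner] + 1 / length(paths)
      }
    }
  }
  b
}

random_small_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.2, 0.9)
  adj <- matrix(0, n, n)
  up <- stats::runif(n * (n - 1) / 2) < p
  adj[upper.tri(adj)] <- as.numeric(up)
  adj + t(adj)
}

# stack of symmetric random connectivity matrices with an optional planted
# mean shift on specific edges (for NBS simulations)
random_fc_stack <- function(n_sub, n_node, shift_edges = NULL, d = 0) {
  lapply(seq_len(n_sub), function(s) {
    m <- matrix(stats::rnorm(n_node^2), n_node)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    if (!is.null(shift_edges)) {
      for (r in seq_len(nrow(shift_edges))) {
        i <- shift_edges[r, 1]; j <- shift_edges[r, 2]
        m[i, j] <- m[j, i] <- m[i, j] + d
      }
    }
    connectivity_matrix(m, "hbo-z")
  })
}

any_significant <- function(nbs_result) {
  any(vapply(nbs_result$components, `[[`, logical(1), "significant"))
}
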