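## Binary graph construction across the proportional-sparsity grid and
## graph-theoretical metrics (standard binary-undirected definitions).
## Shortest paths, betweenness (Brandes) and degree-preserving rewiring are
## delegated to igraph; the test suite checks every metric against
## exhaustive brute-force oracles on small graphs.

#' The proportional-sparsity grid
#'
#' @param lo,hi,step Grid bounds and step; defaults 0.09-0.50 by 0.01
#'   (42 levels). The lower bound is chosen to minimize fragmented
#'   components while preserving topology.
#' @return Object of class `sparsity_grid`: list with `lo`, `hi`, `step`,
#'   `levels`.
#' @export
sparsity_grid <- function(lo = 0.09, hi = 0.50, step = 0.01) {
  abort_if(!(lo > 0 && lo < hi && hi <= 1), "need 0 < lo < hi <= 1")
  levels <- round(seq(lo, hi, by = step), 10)
  structure(list(lo = lo, hi = hi, step = step, levels = levels),
            class = "sparsity_grid")
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                      diag = FALSE)
}

check_adjacency <- function(adj) {
  check_matrix(adj)
  abort_if(!is_symmetric(adj), "adjacency must be symmetric")
  abort_if(any(!adj %in% c(0, 1)), "adjacency must be binary")
  abort_if(any(diag(adj) != 0), "adjacency diagonal must be zero")
  invisible(adj)
}

#' Proportional thresholding of a weighted connectivity matrix
#'
#' Retains the `round(s * N (N - 1) / 2)` strongest upper-triangle weights,
#' symmetrizes, and zeroes the diagonal. Ties are broken deterministically
#' by weight, then by lower ROI-pair index, so the edge sets are nested
#' across increasing sparsity.
#'
#' @param w Symmetric weight matrix (a [connectivity_matrix()] or plain).
#' @param s Sparsity in `(0, 1]`: the fraction of possible edges retained.
#' @return Binary adjacency matrix (0/1) with zero diagonal.
#' @export
threshold_proportional <- function(w, s) {
  w <- unclass(w)
  check_matrix(w)
  abort_if(!is_symmetric(w, 1e-8), "weights must be symmetric")
  abort_if(!(s > 0 && s <= 1), "sparsity must lie in (0, 1]")
  n <- nrow(w)
  pairs <- ut_pairs(n)
  wts <- w[pairs]
  if (length(unique(wts)) == 1) {
    warning("all edge weights equal; retaining edges in index order")
  }
  k <- round(s * nrow(pairs))
  ord <- order(-wts, seq_along(wts))   # strongest first, index tie-break
  adj <- matrix(0, n, n)
  if (k > 0) {
    sel <- pairs[ord[seq_len(k)], , drop = FALSE]
    adj[sel] <- 1
    adj[sel[, 2:1, drop = FALSE]] <- 1
  }
  adj
}

#' Binary clustering coefficient
#'
#' Node CC = 2 * triangles / (k (k - 1)), defined as 0 for degree < 2;
#' global CC is the mean over all nodes.
#'
#' @param adj Binary symmetric adjacency with zero diagonal.
#' @return List: `global` (scalar), `nodal` (per-node vector).
#' @export
clustering_coefficient <- function(adj) {
  check_adjacency(adj)
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2   # triangles through each node
  nodal <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  list(global = mean(nodal), nodal = nodal)
}

## BFS level expansion by boolean matrix products: for the dense graphs of
## this package (<= ~100 nodes) this beats per-call igraph object
## construction by an order of magnitude.
distance_matrix <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  A <- adj != 0
  D[A] <- 1
  reach <- A | diag(TRUE, n)
  frontier <- A
  L <- 1
  while (any(frontier)) {
    nxt <- (frontier %*% adj) > 0
    new <- nxt & !reach
    if (!any(new)) break
    L <- L + 1
    D[new] <- L
    reach <- reach | new
    frontier <- new
  }
  D
}

#' Characteristic path length
#'
#' Mean shortest-path length over all reachable ordered node pairs;
#' unreachable pairs are excluded and counted in the `excluded_pairs`
#' attribute.
#'
#' @param adj Binary symmetric adjacency.
#' @return Scalar CPL with attribute `excluded_pairs`.
#' @export
characteristic_path_length <- function(adj) {
  check_adjacency(adj)
  abort_if(sum(adj) == 0, "empty graph")
  d <- distance_matrix(adj)
  off <- d[row(d) != col(d)]
  reachable <- is.finite(off)
  out <- mean(off[reachable])
  attr(out, "excluded_pairs") <- sum(!reachable)
  out
}

#' Graph efficiency measures
#'
#' `global`: mean of `1 / d(i, j)` over ordered pairs (`1 / Inf = 0`);
#' `nodal`: per node, mean of `1 / d(i, .)` over the other nodes;
#' `local`: per node, global efficiency of the subgraph induced by its
#' neighbors (0 for degree < 2).
#'
#' @param adj Binary symmetric adjacency.
#' @param mode One of "global", "nodal", "local".
#' @return Scalar (global) or per-node vector.
#' @export
efficiency <- function(adj, mode = c("global", "nodal", "local")) {
  mode <- match.arg(mode)
  check_adjacency(adj)
  n <- nrow(adj)
  eglobal_of <- function(a) {
    m <- nrow(a)
    if (m < 2) return(0)
    iv <- 1 / distance_matrix(a)
    diag(iv) <- 0
    sum(iv) / (m * (m - 1))
  }
  if (mode == "local") {
    return(vapply(seq_len(n), function(i) {
      nb <- which(adj[i, ] != 0)
      if (length(nb) < 2) return(0)
      eglobal_of(adj[nb, nb, drop = FALSE])
    }, numeric(1)))
  }
  d <- distance_matrix(adj)
  inv <- 1 / d
  diag(inv) <- 0
  if (mode == "global") {
    if (n < 2) return(0)
    sum(inv) / (n * (n - 1))
  } else {
    rowSums(inv) / (n - 1)
  }
}

#' Degree and betweenness centrality
#'
#' Degree = row sum of the adjacency; betweenness by Brandes' algorithm
#' over all shortest paths, unnormalized.
#'
#' @param adj Binary symmetric adjacency.
#' @return data.frame with columns `node`, `degree`, `betweenness`.
#' @export
centralities <- function(adj) {
  check_adjacency(adj)
  g <- graph_from_adj(adj)
  data.frame(node = seq_len(nrow(adj)),
             degree = as.integer(rowSums(adj)),
             betweenness = igraph::betweenness(g, directed = FALSE,
                                               normalized = FALSE))
}

#' Degree-preserving null networks
#'
#' Maslov-Sneppen double-edge swaps (10 x |E| attempted swaps per null);
#' every null has exactly the original degree sequence. Connectedness is
#' not enforced. Graphs with no swappable edge pairs (e.g. complete graphs
#' or stars) come back unchanged.
#'
#' @param adj Binary symmetric adjacency with >= 2 edges.
#' @param n Number of nulls (default 100).
#' @param seed Integer seed.
#' @return List of adjacency matrices.
#' @export
null_networks <- function(adj, n = 100, seed = 1L) {
  check_adjacency(adj)
  n_edges <- sum(adj) / 2
  abort_if(n_edges < 2, "need at least 2 edges to rewire")
  g <- graph_from_adj(adj)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * n_edges))
      as.matrix(igraph::as_adjacency_matrix(gr, type = "both", sparse = FALSE))
    })
  })
}

#' Small-world index
#'
#' `sigma = (CC / mean null CC) / (CPL / mean null CPL)` against a
#' degree-matched null ensemble. Returns NA (with a warning) when the null
#' mean CC is zero.
#'
#' @param adj Binary symmetric adjacency.
#' @param nulls List of null adjacencies (see [null_networks()]).
#' @return Scalar sigma.
#' @export
small_world_index <- function(adj, nulls) {
  abort_if(length(nulls) == 0, "null ensemble is empty")
  cc <- clustering_coefficient(adj)$global
  cpl <- as.numeric(characteristic_path_length(adj))
  cc_null <- mean(vapply(nulls, function(a) clustering_coefficient(a)$global,
                         numeric(1)))
  cpl_null <- mean(vapply(nulls, function(a)
    as.numeric(characteristic_path_length(a)), numeric(1)))
  if (cc_null == 0) {
    warning("null ensemble has zero mean clustering; sigma undefined")
    return(NA_real_)
  }
  (cc / cc_null) / (cpl / cpl_null)
}

#' Integrate a metric curve over the sparsity grid
#'
#' Trapezoidal integral of one value per sparsity level across the grid
#' (no normalization by the range width).
#'
#' @param values Numeric vector, one finite value per grid level.
#' @param grid A [sparsity_grid()].
#' @return Scalar AUC.
#' @export
auc_over_sparsity <- function(values, grid = sparsity_grid()) {
  abort_if(length(values) != length(grid$levels),
           "need one value per level (%d values for %d levels)",
           length(values), length(grid$levels))
  bad <- which(!is.finite(values))
  abort_if(length(bad) > 0, "missing/non-finite values at levels %s",
           paste(grid$levels[bad], collapse = ", "))
  trapz_integral(grid$levels, values)
}

#' Sparsity-integrated graph metrics of one connectivity matrix
#'
#' Thresholds the weights at every level of the grid, computes global
#' metrics (CC, CPL, Eglobal, SWI) and nodal metrics (degree, betweenness,
#' nodal CC, nodal local efficiency, nodal efficiency), and integrates each
#' metric curve to its AUC.
#'
#' @param w Weighted [connectivity_matrix()] (or plain symmetric matrix).
#' @param grid A [sparsity_grid()].
#' @param n_null Null networks per level for the small-world index
#'   (default 100); 0 skips SWI.
#' @param seed Seed for the null ensembles.
#' @return List: `global` (data.frame level x metric), `nodal` (list of
#'   level x node matrices), `auc` (list: `global` named vector, `nodal`
#'   named list of per-node vectors), `grid`.
#' @export
graph_metrics <- function(w, grid = sparsity_grid(), n_null = 100, seed = 1L) {
  levels <- grid$levels
  n <- nrow(w)
  glob <- data.frame(sparsity = levels, cc = NA_real_, cpl = NA_real_,
                     eglobal = NA_real_, swi = NA_real_)
  nodal_names <- c("degree", "betweenness", "nodal_cc", "nodal_elocal",
                   "nodal_eff")
  nodal <- lapply(nodal_names, function(m)
    matrix(NA_real_, length(levels), n))
  names(nodal) <- nodal_names
  for (li in seq_along(levels)) {
    adj <- threshold_proportional(w, levels[li])
    g <- graph_from_adj(adj)
    d <- distance_matrix(adj)
    inv <- 1 / d; diag(inv) <- 0
    off <- d[row(d) != col(d)]
    cc <- clustering_coefficient(adj)
    glob$cc[li] <- cc$global
    glob$cpl[li] <- mean(off[is.finite(off)])
    glob$eglobal[li] <- sum(inv) / (n * (n - 1))
    if (n_null > 0) {
      nulls <- null_networks(adj, n_null, derive_seed(seed, li))
      glob$swi[li] <- small_world_index(adj, nulls)
    }
    nodal$degree[li, ] <- rowSums(adj)
    nodal$betweenness[li, ] <- igraph::betweenness(g, directed = FALSE,
                                                   normalized = FALSE)
    nodal$nodal_cc[li, ] <- cc$nodal
    nodal$nodal_elocal[li, ] <- efficiency(adj, "local")
    nodal$nodal_eff[li, ] <- rowSums(inv) / (n - 1)
  }
  auc_global <- vapply(c("cc", "cpl", "eglobal", if (n_null > 0) "swi"),
                       function(m) auc_over_sparsity(glob[[m]], grid),
                       numeric(1))
  auc_nodal <- lapply(nodal, function(mat)
    apply(mat, 2, auc_over_sparsity, grid = grid))
  list(global = glob, nodal = nodal,
       auc = list(global = auc_global, nodal = auc_nodal), grid = grid)
}
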