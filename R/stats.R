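## Group inference. Edge-level contrasts: network-based statistic (NBS)
## with per-subject sign-flip permutations of the paired differences.
## Metric-level contrasts: one-way repeated-measures ANOVA with BH-FDR over
## ROIs and Bonferroni-corrected pairwise post hocs.

## Stack a list of per-subject connectivity matrices into subjects x edges
## (upper triangle, row-major pair order).
stack_edges <- function(mats) {
  n <- nrow(mats[[1]])
  pairs <- ut_pairs(n)
  res <- vapply(mats, function(m) unclass(m)[pairs], numeric(nrow(pairs)))
  out <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
  list(data = out, pairs = pairs, n_nodes = n)
}

#' Edge-wise paired t tests
#'
#' Two-sided paired t per upper-triangle edge between two matched stacks of
#' connectivity matrices; edges with zero-variance differences are excluded
#' from the suprathreshold mask (and listed in `excluded`).
#'
#' @param cond_a,cond_b Lists of per-subject [connectivity_matrix()] (same
#'   subjects, same order, n >= 3).
#' @param alpha Edge screening threshold on the two-sided p (default 0.001).
#' @return List: `t`, `p` (per edge), `mask` (p < alpha), `pairs` (edge
#'   index matrix), `excluded` (edge indices), `n_nodes`, `df`.
#' @export
paired_t_edges <- function(cond_a, cond_b, alpha = 0.001) {
  abort_if(length(cond_a) != length(cond_b),
           "conditions have different subject counts")
  n_sub <- length(cond_a)
  abort_if(n_sub < 3, "need at least 3 matched subjects")
  a <- stack_edges(cond_a)
  b <- stack_edges(cond_b)
  abort_if(a$n_nodes != b$n_nodes, "node counts differ between conditions")
  d <- a$data - b$data
  m <- colMeans(d)
  v <- (colSums(d^2) - n_sub * m^2) / (n_sub - 1)
  v <- pmax(v, 0)
  excluded <- which(v < .Machine$double.eps)
  tt <- rep(0, length(m))
  ok <- setdiff(seq_along(m), excluded)
  tt[ok] <- m[ok] / sqrt(v[ok] / n_sub)
  p <- 2 * stats::pt(-abs(tt), df = n_sub - 1)
  p[excluded] <- 1
  mask <- p < alpha
  mask[excluded] <- FALSE
  list(t = tt, p = p, mask = mask, pairs = a$pairs, excluded = excluded,
       n_nodes = a$n_nodes, df = n_sub - 1)
}

## Union-find over nodes; returns max component edge count and the
## component id per edge.
uf_components <- function(edge_pairs, n_nodes) {
  storage.mode(edge_pairs) <- "integer"
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(edge_pairs))) {
    ri <- find(edge_pairs[r, 1])
    rj <- find(edge_pairs[r, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(edge_pairs[, 1], find, integer(1))
  comp <- match(roots, unique(roots))
  sizes <- tabulate(comp)
  list(edge_component = comp, sizes = sizes)
}

#' Connected components of a suprathreshold edge set
#'
#' Clusters suprathreshold edges into spatially contiguous components;
#' component size is its aggregate edge count.
#'
#' @param mask Logical vector over upper-triangle edges, or an integer edge
#'   matrix (one ROI pair per row).
#' @param n_nodes Number of nodes (default 46).
#' @param pairs Edge index matrix matching `mask` (default: upper triangle
#'   of an `n_nodes` graph in row-major order).
#' @return List of components, each a list with `edges` (pair matrix) and
#'   `size` (edge count); empty list for an empty mask.
#' @export
components_from_edges <- function(mask, n_nodes = 46, pairs = NULL) {
  if (is.matrix(mask)) {
    ep <- mask
  } else {
    if (is.null(pairs)) pairs <- ut_pairs(n_nodes)
    ep <- pairs[mask, , drop = FALSE]
  }
  if (nrow(ep) == 0) return(list())
  uf <- uf_components(ep, n_nodes)
  lapply(seq_along(uf$sizes), function(k) {
    list(edges = ep[uf$edge_component == k, , drop = FALSE],
         size = uf$sizes[k])
  })
}

max_component_size <- function(mask, pairs, n_nodes) {
  ep <- pairs[mask, , drop = FALSE]
  if (nrow(ep) == 0) return(0L)
  max(uf_components(ep, n_nodes)$sizes)
}

#' Network-based statistic
#'
#' Screens edges with paired t tests at `edge_alpha`, clusters
#' suprathreshold edges into connected components, and assesses each
#' observed component's edge count against a permutation null of maximal
#' component sizes. The paired design is permuted by per-subject sign flips
#' of the difference matrices. Permutation p uses the +1 correction:
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`. The default component
#' alpha 0.05/3 Bonferroni-accounts for the three connectivity families
#' analyzed (HbO, HbR, EEG PLV).
#'
#' @inheritParams paired_t_edges
#' @param edge_alpha Edge screening threshold (default 0.001).
#' @param n_perm Number of permutations (default 10000).
#' @param comp_alpha Component-level significance threshold (default 0.05/3).
#' @param seed Integer seed for the sign flips.
#' @return Object of class `nbs_result`: list with `components` (each with
#'   `edges`, `size`, `p`, `significant`), `mask`, `t`, `null_distribution`
#'   (length `n_perm`), and `params`.
#' @export
nbs <- function(cond_a, cond_b, edge_alpha = 0.001, n_perm = 10000,
                comp_alpha = 0.05 / 3, seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  scr <- paired_t_edges(cond_a, cond_b, edge_alpha)
  n_sub <- length(cond_a)
  comps <- components_from_edges(scr$mask, scr$n_nodes, scr$pairs)
  # vectorized sign-flip null of the maximal component size
  a <- stack_edges(cond_a); b <- stack_edges(cond_b)
  d <- a$data - b$data
  ss <- colSums(d^2)
  tcrit <- stats::qt(1 - edge_alpha / 2, df = n_sub - 1)
  signs <- with_seed(derive_seed(seed, 11L),
                     matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                            n_perm, n_sub))
  msum <- signs %*% d / n_sub                      # permuted means
  vperm <- sweep(-n_sub * msum^2, 2, ss, "+") / (n_sub - 1)
  vperm[vperm < .Machine$double.eps] <- Inf        # zero-variance edges: t = 0
  tperm <- abs(msum) / sqrt(vperm / n_sub)
  null_dist <- integer(n_perm)
  supra <- tperm > tcrit
  hit_rows <- which(rowSums(supra) > 0)
  for (r in hit_rows) {
    null_dist[r] <- max_component_size(supra[r, ], scr$pairs, scr$n_nodes)
  }
  components <- lapply(comps, function(cp) {
    p <- (1 + sum(null_dist >= cp$size)) / (1 + n_perm)
    c(cp, list(p = p, significant = p < comp_alpha))
  })
  structure(list(components = components, mask = scr$mask, t = scr$t,
                 pairs = scr$pairs, null_distribution = null_dist,
                 params = list(edge_alpha = edge_alpha, n_perm = n_perm,
                               comp_alpha = comp_alpha, seed = seed,
                               n_subjects = n_sub)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  sig <- sum(vapply(x$components, `[[`, logical(1), "significant"))
  cat(sprintf("<nbs_result> %d suprathreshold edges, %d component(s), %d significant (alpha = %.4g, %d perms)\n",
              sum(x$mask), length(x$components), sig,
              x$params$comp_alpha, x$params$n_perm))
  invisible(x)
}

## Greenhouse-Geisser sphericity epsilon of a subjects x conditions table.
gg_epsilon <- function(values) {
  S <- stats::cov(values)
  k <- ncol(values)
  num <- (k * mean(diag(S)) - mean(S))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2)
  if (den <= 0) return(1)
  min(1, max(1 / (k - 1), num / den))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way RM-ANOVA via `stats::aov` with an
#' `Error(subject)` stratum: `F = MS_condition / MS_error` on
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom. No sphericity correction
#' is applied; the Greenhouse-Geisser epsilon is reported for transparency.
#'
#' @param values Numeric matrix, subjects x conditions (complete cases);
#'   column names are the condition labels.
#' @return List: `F`, `df1`, `df2`, `p`, `ms_condition`, `ms_error`,
#'   `epsilon`, `flagged` (TRUE when MS_error is zero with unequal means;
#'   p is then reported as 0).
#' @export
rm_anova <- function(values) {
  abort_if(!is.matrix(values) || anyNA(values),
           "values must be a complete subjects x conditions matrix")
  n <- nrow(values); k <- ncol(values)
  abort_if(n < 3, "need at least 3 subjects")
  abort_if(k < 2, "need at least 2 conditions")
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), k)),
                   condition = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_cond <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  flagged <- FALSE
  if (ms_err < .Machine$double.eps * max(1, ms_cond)) {
    if (ms_cond < .Machine$double.eps) {
      fstat <- 0; p <- 1
    } else {
      fstat <- Inf; p <- 0; flagged <- TRUE
    }
  } else {
    fstat <- ms_cond / ms_err
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  list(F = fstat, df1 = df1, df2 = df2, p = p,
       ms_condition = ms_cond, ms_error = ms_err,
       epsilon = gg_epsilon(values), flagged = flagged)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR over a family of p-values; rejection at level `q` is
#' equivalent to adjusted p <= q.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List: `adjusted` (BH-adjusted p), `rejected` (logical mask).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) {
    return(list(adjusted = numeric(0), rejected = logical(0)))
  }
  abort_if(any(pvalues < 0 | pvalues > 1), "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Bonferroni-corrected pairwise post hoc tests
#'
#' Paired t test for each phase pair; raw p multiplied by the number of
#' pairs and capped at 1. Identical phases give adjusted p = 1; a constant
#' nonzero shift (zero-variance difference) gives p = 0, flagged.
#'
#' @param values Subjects x conditions matrix (named columns).
#' @param pairs List of length-2 character vectors of column names; default
#'   all pairs in column order.
#' @return data.frame: `a`, `b`, `t`, `p_raw`, `p_adjusted`, `flagged`.
#' @export
bonferroni_posthoc <- function(values, pairs = NULL) {
  cn <- colnames(values)
  if (is.null(cn)) cn <- colnames(values) <- paste0("c", seq_len(ncol(values)))
  if (is.null(pairs)) {
    pairs <- utils::combn(cn, 2, simplify = FALSE)
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    d <- values[, pr[1]] - values[, pr[2]]
    if (stats::sd(d) < .Machine$double.eps) {
      if (abs(mean(d)) < .Machine$double.eps) {
        data.frame(a = pr[1], b = pr[2], t = 0, p_raw = 1,
                   p_adjusted = 1, flagged = FALSE)
      } else {
        data.frame(a = pr[1], b = pr[2], t = Inf, p_raw = 0,
                   p_adjusted = 0, flagged = TRUE)
      }
    } else {
      tt <- stats::t.test(values[, pr[1]], values[, pr[2]], paired = TRUE)
      data.frame(a = pr[1], b = pr[2], t = unname(tt$statistic),
                 p_raw = tt$p.value,
                 p_adjusted = min(1, tt$p.value * m), flagged = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Nodal RM-ANOVA across ROIs with FDR correction
#'
#' Runs [rm_anova()] per ROI on a subjects x phases x ROIs array of nodal
#' metric values and applies BH-FDR over the ROI family, plus
#' Bonferroni-corrected post hocs for ROIs only.
#'
#' @param values 3-d array: subjects x phases x ROIs (dimnames used when
#'   present).
#' @param q FDR level over the 46-ROI family (default 0.05).
#' @return data.frame, one row per ROI: `roi`, `F`, `df1`, `df2`, `p`,
#'   `p_fdr`, `rejected`, `epsilon`.
#' @export
nodal_rm_anova <- function(values, q = 0.05) {
  abort_if(length(dim(values)) != 3, "values must be subjects x phases x ROIs")
  n_roi <- dim(values)[3]
  labels <- dimnames(values)[[3]]
  if (is.null(labels)) labels <- sprintf("roi%02d", seq_len(n_roi))
  rows <- lapply(seq_len(n_roi), function(r) {
    res <- rm_anova(values[, , r])
    data.frame(roi = labels[r], F = res$F, df1 = res$df1, df2 = res$df2,
               p = res$p, epsilon = res$epsilon)
  })
  out <- do.call(rbind, rows)
  corr <- fdr_bh(out$p, q)
  out$p_fdr <- corr$adjusted
  out$rejected <- corr$rejected
  out
}
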