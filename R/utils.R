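## Internal helpers shared across modules.

#' Stop with a formatted validation message
#' @noRd
abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

#' Check that x is a finite numeric matrix
#' @noRd
check_matrix <- function(x, name = deparse(substitute(x))) {
  abort_if(!is.matrix(x) || !is.numeric(x), "%s must be a numeric matrix", name)
  abort_if(any(!is.finite(x)), "%s contains non-finite values", name)
  invisible(x)
}

#' Symmetry check with tolerance
#' @noRd
is_symmetric <- function(x, tol = 1e-10) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) <= tol
}

#' Trapezoidal integral (thin wrapper so the rule is stated once)
#' @noRd
trapz_integral <- function(x, y) {
  pracma::trapz(x, y)
}

#' A local RNG scope: run expr with a seed without touching the global stream
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Upper-triangle index pairs of an n x n matrix, column-major stable order
#' @noRd
ut_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
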