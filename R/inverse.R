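## Linear inverse solutions on toy leadfields. Fixed-orientation (scalar)
## sources keep the sLORETA standardization scalar per source. Data and
## leadfield are projected to the average-reference space before inversion,
## matching the EEG referencing convention; the regularized operator is
## inverted with a pseudo-inverse since that projector is rank-deficient.

avg_ref_projector <- function(m) diag(m) - matrix(1 / m, m, m)

sensor_matrix <- function(sensors) {
  if (inherits(sensors, "sensor_recording")) return(sensors$data)
  if (inherits(sensors, "epoch_set")) {
    d <- sensors$epochs
    # concatenate kept epochs along time
    return(matrix(aperm(d, c(2, 3, 1)), dim(d)[2]))
  }
  if (is.matrix(sensors)) return(sensors)
  stop("sensors must be a sensor_recording, epoch_set or matrix")
}

#' Default inverse regularization
#'
#' `lambda = trace(K K^T) / (n_sensors * SNR^2)` with an assumed
#' signal-to-noise ratio of 3.
#'
#' @param lf A leadfield.
#' @param snr Assumed amplitude SNR.
#' @return Scalar regularization parameter.
#' @export
default_lambda <- function(lf, snr = 3) {
  K <- lf$gain
  sum(K * K) / (nrow(K) * snr^2)
}

#' sLORETA inverse solution
#'
#' Minimum-norm estimate `J = K^T (K K^T + lambda H)^+ V` in the
#' average-reference space (`H` the average-reference projector),
#' standardized per source by the corresponding diagonal element of the
#' resolution matrix `R = K^T (K K^T + lambda H)^+ K`. For a single
#' noiseless source the argmax of the standardized power lies at the true
#' source for any `lambda >= 0` (the classic zero-localization-error
#' property), which the test suite verifies exhaustively on toy problems.
#'
#' @param sensors A [sensor_recording()], [epoch_set()] or channels x
#'   samples matrix.
#' @param lf A [make_toy_leadfield()] leadfield.
#' @param lambda Regularization (>= 0); default from [default_lambda()].
#' @return List: `sources` (sources x samples, standardized), `raw`
#'   (unstandardized minimum-norm series), `power` (standardized power per
#'   source, averaged over time), `lambda`.
#' @export
sloreta <- function(sensors, lf, lambda = default_lambda(lf)) {
  V <- sensor_matrix(sensors)
  K <- lf$gain
  abort_if(nrow(V) != nrow(K),
           "sensor count (%d) does not match leadfield rows (%d)",
           nrow(V), nrow(K))
  abort_if(lambda < 0, "lambda must be non-negative")
  m <- nrow(K)
  H <- avg_ref_projector(m)
  Kc <- H %*% K
  Vc <- H %*% V
  Cinv <- tryCatch(MASS::ginv(Kc %*% t(Kc) + lambda * H),
                   error = function(e)
                     stop("singular regularized operator; increase lambda",
                          call. = FALSE))
  M <- t(Kc) %*% Cinv
  J <- M %*% Vc
  Rdiag <- rowSums(M * t(Kc))   # diag of M %*% Kc
  abort_if(any(Rdiag <= 0), "resolution diagonal not positive; increase lambda")
  Jstd <- J / sqrt(Rdiag)
  list(sources = Jstd, raw = J,
       power = rowMeans(Jstd^2), lambda = lambda)
}

#' Depth-weighted minimum-norm estimate (wMNE)
#'
#' Weighted minimum norm with source weights `w_s = ||k_s||^(-2 gamma)`:
#' `J = W K^T (K W K^T + lambda I)^+ V`, `W = diag(w)`. `gamma = 0`
#' reduces exactly to the unweighted MNE; `gamma = 0.5` counteracts the
#' superficial-source bias of the unweighted solution.
#'
#' @inheritParams sloreta
#' @param gamma Depth-weighting exponent (>= 0, default 0.5).
#' @return List: `sources` (sources x samples), `power`, `weights`,
#'   `lambda`, `gamma`.
#' @export
wmne <- function(sensors, lf, lambda = default_lambda(lf), gamma = 0.5) {
  V <- sensor_matrix(sensors)
  K <- lf$gain
  abort_if(nrow(V) != nrow(K),
           "sensor count (%d) does not match leadfield rows (%d)",
           nrow(V), nrow(K))
  abort_if(gamma < 0, "gamma must be non-negative")
  abort_if(lambda < 0, "lambda must be non-negative")
  w <- colSums(K^2)^(-gamma)   # ||k_s||^(-2 gamma)
  KW <- sweep(K, 2, w, "*")    # K W
  Cinv <- tryCatch(MASS::ginv(KW %*% t(K) + lambda * diag(nrow(K))),
                   error = function(e)
                     stop("singular regularized operator; increase lambda",
                          call. = FALSE))
  J <- sweep(t(K), 1, w, "*") %*% Cinv %*% V
  list(sources = J, power = rowMeans(J^2), weights = w,
       lambda = lambda, gamma = gamma)
}

#' Aggregate source series into atlas ROIs
#'
#' Per ROI, the sign-aligned arithmetic mean of its member source series:
#' a member is sign-flipped when it correlates negatively with the ROI's
#' first principal temporal component, preventing cancellation of
#' anti-phase members.
#'
#' @param src Sources x samples matrix (e.g. `$sources` from [sloreta()]).
#' @param mask An `atlas_mask` with a `source_roi` assignment
#'   (see [assign_sources()]).
#' @param rate Sampling rate of the source series.
#' @param meta Tag list passed to the result.
#' @return A [roi_timeseries()] with one row per mask label, in mask order.
#' @export
roi_aggregate <- function(src, mask, rate, meta = list()) {
  abort_if(is.null(mask$source_roi), "mask carries no source-to-ROI assignment")
  abort_if(length(mask$source_roi) != nrow(src),
           "assignment length (%d) does not match source count (%d)",
           length(mask$source_roi), nrow(src))
  n_roi <- length(mask$labels)
  empty <- setdiff(seq_len(n_roi), unique(mask$source_roi))
  abort_if(length(empty) > 0, "empty ROI(s): %s",
           paste(mask$labels[empty], collapse = ", "))
  out <- matrix(0, n_roi, ncol(src))
  for (r in seq_len(n_roi)) {
    member <- src[mask$source_roi == r, , drop = FALSE]
    if (nrow(member) == 1) {
      out[r, ] <- member
      next
    }
    pc1 <- svd(member, nu = 0, nv = 1)$v[, 1]
    signs <- vapply(seq_len(nrow(member)), function(i) {
      s <- sum(member[i, ] * pc1)
      if (s < 0) -1 else 1
    }, numeric(1))
    agg <- colMeans(member * signs)
    # overall sign convention: agree with the first member
    if (sum(agg * member[1, ]) < 0) agg <- -agg
    out[r, ] <- agg
  }
  roi_timeseries(out, rate, mask$labels, meta = meta)
}
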