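## Functional connectivity. EEG: band-limited analytic phase (FFT Hilbert)
## and phase-locking value, computed per 2-s epoch and averaged; fNIRS:
## Pearson correlation of the slow hemoglobin series with Fisher r-to-z.

#' Cut a continuous ROI series into fixed-length epochs
#'
#' @param roi A [roi_timeseries()] with a 2-d data matrix.
#' @param length Epoch length in seconds (default 2).
#' @return A [roi_timeseries()] whose data is epochs x ROIs x samples.
#' @export
epoch_roi <- function(roi, length = 2) {
  abort_if(base::length(dim(roi$data)) != 2, "roi series is already epoched")
  spe <- round(length * roi$rate)
  n_ep <- floor(ncol(roi$data) / spe)
  abort_if(n_ep < 1, "series shorter than one epoch")
  arr <- array(NA_real_, c(n_ep, nrow(roi$data), spe))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- roi$data[, ((e - 1) * spe + 1):(e * spe)]
  }
  roi_timeseries(arr, roi$rate, roi$roi_labels, roi$meta)
}

## Zero-phase FFT band filter with a 0.5 Hz raised-cosine transition just
## inside the stop bands. Exact zero gain beyond the transition; no phase
## distortion at any frequency.
fft_bandpass <- function(x, fs, lo, hi, transition = 0.5) {
  n <- length(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  w <- numeric(n)
  w[f >= lo & f <= hi] <- 1
  tl <- f >= lo - transition & f < lo
  w[tl] <- 0.5 * (1 - cos(pi * (f[tl] - (lo - transition)) / transition))
  th <- f > hi & f <= hi + transition
  w[th] <- 0.5 * (1 + cos(pi * (f[th] - hi) / transition))
  Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
}

#' Band-limit ROI series to a canonical EEG band
#'
#' Zero-phase band-pass at the band's printed edges (delta 1-4, theta 4-8,
#' alpha 8-15, beta 15-25, gamma 25-45 Hz), realized as an FFT mask with a
#' narrow raised-cosine transition.
#'
#' @param roi A [roi_timeseries()] (continuous or epoched).
#' @param band Band label.
#' @return Filtered [roi_timeseries()]; `meta$band` records the band.
#' @export
band_filter <- function(roi, band = c("delta", "theta", "alpha", "beta", "gamma")) {
  band <- match.arg(band)
  b <- eeg_bands()
  i <- match(band, b$band)
  abort_if(b$hi[i] >= roi$rate / 2,
           "band edge %g Hz >= Nyquist (%g Hz)", b$hi[i], roi$rate / 2)
  d <- roi$data
  if (length(dim(d)) == 2) {
    for (r in seq_len(nrow(d))) d[r, ] <- fft_bandpass(d[r, ], roi$rate,
                                                       b$lo[i], b$hi[i])
  } else {
    for (e in seq_len(dim(d)[1])) {
      for (r in seq_len(dim(d)[2])) {
        d[e, r, ] <- fft_bandpass(d[e, r, ], roi$rate, b$lo[i], b$hi[i])
      }
    }
  }
  roi$data <- d
  roi$meta$band <- band
  roi
}

#' Instantaneous phase of the analytic signal
#'
#' FFT-based Hilbert transform; phase in `(-pi, pi]`. The first and last
#' 10% of each epoch should be discarded downstream (see [plv()]).
#'
#' @param x Numeric vector (band-limited).
#' @return Phase series in radians.
#' @export
analytic_phase <- function(x) {
  abort_if(stats::sd(x) < .Machine$double.eps, "undefined phase: constant input")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  Arg(z)
}

trim_idx <- function(n, trim) {
  k <- floor(trim * n)
  (1 + k):(n - k)
}

#' Phase-locking value
#'
#' `PLV = |mean_t exp(i (phi_i - phi_j))|`, computed per epoch and averaged
#' across epochs. Amplitude-independent synchrony in `[0, 1]`.
#'
#' @param phase_i,phase_j Phase series: numeric vectors (one epoch) or
#'   matrices with one epoch per row.
#' @param trim Fraction of samples discarded at each epoch edge
#'   (Hilbert edge effects); default 0.1.
#' @return Scalar PLV in `[0, 1]`.
#' @export
plv <- function(phase_i, phase_j, trim = 0.1) {
  if (is.vector(phase_i)) phase_i <- matrix(phase_i, nrow = 1)
  if (is.vector(phase_j)) phase_j <- matrix(phase_j, nrow = 1)
  abort_if(!identical(dim(phase_i), dim(phase_j)),
           "phase series have mismatched lengths")
  abort_if(nrow(phase_i) < 1, "need at least one epoch")
  idx <- trim_idx(ncol(phase_i), trim)
  vals <- vapply(seq_len(nrow(phase_i)), function(e) {
    d <- phase_i[e, idx] - phase_j[e, idx]
    Mod(mean(exp(1i * d)))
  }, numeric(1))
  mean(vals)
}

#' Band-wise PLV connectivity matrix
#'
#' All ROI pairs of an epoched, band-limited ROI series: analytic phase per
#' epoch (edges trimmed), per-epoch PLV, averaged across epochs. Symmetric
#' with unit diagonal.
#'
#' @param roi An epoched [roi_timeseries()] (epochs x ROIs x samples),
#'   already band-limited (see [band_filter()], [epoch_roi()]).
#' @param band Band label recorded on the result (defaults to `meta$band`).
#' @param trim Edge-trim fraction per epoch.
#' @return A [connectivity_matrix()] with modality `plv-<band>`.
#' @export
plv_matrix <- function(roi, band = roi$meta$band, trim = 0.1) {
  d <- roi$data
  abort_if(length(dim(d)) != 3, "plv_matrix needs an epoched ROI series")
  n_ep <- dim(d)[1]; n_roi <- dim(d)[2]; n_s <- dim(d)[3]
  abort_if(n_roi < 2, "need at least 2 ROIs")
  idx <- trim_idx(n_s, trim)
  acc <- matrix(0, n_roi, n_roi)
  for (e in seq_len(n_ep)) {
    ph <- matrix(NA_real_, n_roi, n_s)
    for (r in seq_len(n_roi)) {
      ph[r, ] <- tryCatch(analytic_phase(d[e, r, ]),
                          error = function(err)
                            stop(sprintf("ROI %s, epoch %d: %s",
                                         roi$roi_labels[r], e,
                                         conditionMessage(err)), call. = FALSE))
    }
    U <- exp(1i * ph[, idx, drop = FALSE])
    acc <- acc + Mod(U %*% Conj(t(U))) / length(idx)
  }
  vals <- acc / n_ep
  vals <- (vals + t(vals)) / 2
  vals <- pmin(pmax(vals, 0), 1)
  diag(vals) <- 1
  connectivity_matrix(vals, paste0("plv-", if (is.null(band)) "band" else band),
                      roi$roi_labels, roi$meta)
}

#' Pearson correlation connectivity for hemoglobin series
#'
#' Pairwise Pearson r between ROI hemoglobin time courses. Zero-variance
#' ROIs produce 0 entries, flagged in the `missing_rois` attribute (with a
#' warning).
#'
#' @param hb A [roi_timeseries()] (ROIs x samples, >= 20 samples).
#' @param chromophore "hbo" or "hbr" (tag for the result).
#' @return A [connectivity_matrix()] of r values (modality `<chrom>-r`).
#' @export
pearson_fc <- function(hb, chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  x <- hb$data
  abort_if(length(dim(x)) != 2, "pearson_fc expects a continuous ROI series")
  abort_if(ncol(x) < 20, "need at least 20 samples per series")
  v <- apply(x, 1, stats::var)
  flat <- which(v < .Machine$double.eps)
  r <- suppressWarnings(stats::cor(t(x)))
  if (length(flat) > 0) {
    warning(sprintf("zero-variance ROI(s) %s: entries set to 0 and flagged",
                    paste(hb$roi_labels[flat], collapse = ", ")))
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  out <- connectivity_matrix(r, paste0(chromophore, "-r"), hb$roi_labels,
                             hb$meta)
  attr(out, "missing_rois") <- unname(flat)
  out
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' `z = atanh(r)`, variance-stabilizing the correlation distribution;
#' `|r| = 1` is capped at `atanh(1 - 1e-15)` to keep downstream
#' thresholding finite. The diagonal is excluded (set to 0).
#'
#' @param r_matrix A correlation [connectivity_matrix()] or plain matrix.
#' @return A [connectivity_matrix()] of z values (modality `<chrom>-z`).
#' @export
fisher_z <- function(r_matrix) {
  r <- unclass(r_matrix)
  abort_if(any(abs(r) > 1 + 1e-9), "|r| > 1 is not a correlation")
  cap <- 1 - 1e-15
  z <- atanh(pmin(pmax(r, -cap), cap))
  diag(z) <- 0
  modality <- attr(r_matrix, "modality")
  modality <- if (is.null(modality)) "z" else sub("-r$", "-z", modality)
  connectivity_matrix(z, modality, rownames(r),
                      if (is.null(attr(r_matrix, "meta"))) list()
                      else attr(r_matrix, "meta"))
}
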