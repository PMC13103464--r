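## Signal conditioning for both modalities. All filters are zero-phase
## (forward-backward Butterworth via signal::filtfilt). EEG: band-pass,
## downsample, bad-channel detection and spherical-spline interpolation,
## 2-s epoching with +/-100 uV rejection, common average reference.
## fNIRS: optical-density conversion, temporal-derivative motion repair,
## 0.01-0.1 Hz band-pass, modified Beer-Lambert inversion.

## Zero-phase filtering with odd-reflection padding: signal::filtfilt starts
## from zero filter state, which leaves edge transients on signals with
## nonzero boundary values; padding pushes the transients outside the data.
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  np <- min(n - 1, 2000)
  front <- 2 * x[1] - x[(np + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(filt, c(front, x, back))
  y[(np + 1):(np + n)]
}

filtfilt_rows <- function(x, filt) {
  t(apply(x, 1, function(row) filtfilt_padded(filt, row)))
}

## channels x time view of a recording or epoch set (epochs concatenated)
flat_channels <- function(x) {
  if (inherits(x, "sensor_recording")) return(x$data)
  if (inherits(x, "epoch_set")) {
    d <- x$epochs
    return(matrix(aperm(d, c(2, 3, 1)), dim(d)[2]))
  }
  stop("expected a sensor_recording or epoch_set")
}

#' Zero-phase EEG band-pass filter
#'
#' High-pass (order 4) and low-pass (order 9) Butterworth sections applied
#' forward-backward. The split into two sections and the section orders are
#' chosen so the two-pass magnitude response is down at least 40 dB at
#' `0.5 * lo` and at `4/3 * hi` (60 Hz line frequency for the default
#' 45 Hz edge), while a single band-pass design of that order would be
#' numerically fragile at the low edge.
#'
#' @param rec A [sensor_recording()].
#' @param lo,hi Band edges in Hz (default 1-45).
#' @return Filtered recording.
#' @export
eeg_bandpass <- function(rec, lo = 1, hi = 45) {
  abort_if(hi >= rec$rate / 2, "upper edge %g Hz >= Nyquist (%g Hz)",
           hi, rec$rate / 2)
  abort_if(lo <= 0 || lo >= hi, "band edges must satisfy 0 < lo < hi")
  hp <- signal::butter(4, lo / (rec$rate / 2), type = "high")
  lp <- signal::butter(9, hi / (rec$rate / 2), type = "low")
  x <- filtfilt_rows(rec$data, hp)
  x <- filtfilt_rows(x, lp)
  rec$data <- x
  rec
}

#' Anti-aliased downsampling
#'
#' Low-pass filters at 80% of the target Nyquist (order-8 Butterworth,
#' zero phase), then resamples by linear interpolation on the new time
#' grid. Duration is preserved to within one sample.
#'
#' @param rec A [sensor_recording()].
#' @param target Target rate in Hz (default 256).
#' @return Recording at the target rate.
#' @export
downsample <- function(rec, target = 256) {
  abort_if(target >= rec$rate, "target rate must be below the current rate")
  lp <- signal::butter(8, 0.8 * (target / 2) / (rec$rate / 2), type = "low")
  x <- filtfilt_rows(rec$data, lp)
  n <- ncol(x)
  t_old <- (seq_len(n) - 1) / rec$rate
  t_new <- seq(0, t_old[n], by = 1 / target)
  y <- t(apply(x, 1, function(row) stats::approx(t_old, row, xout = t_new)$y))
  rec$data <- y
  rec$rate <- target
  rec
}

#' Detect bad channels by robust variance/kurtosis outlier scores
#'
#' Flags channels whose log-variance or kurtosis robust z-score
#' (median/MAD) exceeds `z_thresh`, plus flatlines (variance < 1e-12).
#'
#' @param rec A [sensor_recording()] or [epoch_set()] with >= 8 channels.
#' @param z_thresh Robust z threshold (default 3).
#' @return Integer vector of flagged channel indices (possibly empty).
#' @export
detect_bad_channels <- function(rec, z_thresh = 3.0) {
  x <- flat_channels(rec)
  abort_if(nrow(x) < 8, "need at least 8 channels")
  n <- ncol(x)
  v <- apply(x, 1, stats::var)
  flat <- which(v < 1e-12)
  # scale floored by the statistic's own sampling noise, so homogeneous
  # channels are not flagged on chance fluctuations of the MAD
  robust_z <- function(s, floor_sd) {
    s[!is.finite(s)] <- stats::median(s[is.finite(s)])
    med <- stats::median(s)
    m <- max(stats::mad(s), floor_sd)
    (s - med) / m
  }
  lv <- robust_z(log(pmax(v, 1e-300)), sqrt(2 / n))
  ku <- robust_z(apply(x, 1, e1071::kurtosis), sqrt(24 / n))
  bad <- sort(unique(c(flat, which(abs(lv) > z_thresh | abs(ku) > z_thresh))))
  abort_if(length(bad) == nrow(x), "recording unusable: all channels flagged")
  bad
}

## Perrin-style spherical spline basis: g(x) = sum_{l=1}^{L}
## (2l+1) / (l (l+1))^m P_l(x) / (4 pi), m = 4.
spline_g <- function(x, m = 4, L = 50) {
  # Legendre recursion, vectorized over x
  p_prev <- rep(1, length(x))  # P_0
  p_cur <- x                   # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (l in 2:L) {
    p_next <- ((2 * l - 1) * x * p_cur - (l - 1) * p_prev) / l
    acc <- acc + (2 * l + 1) / (l * (l + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces flagged channels with an order-4 spherical-spline estimate from
#' the good channels (ridge regularization 1e-5), using unit-sphere channel
#' positions from the channel table.
#'
#' @param rec A [sensor_recording()] or [epoch_set()] whose channel table
#'   has `x`, `y`, `z`.
#' @param bad Integer indices of channels to replace (from
#'   [detect_bad_channels()]).
#' @param lambda Ridge regularization of the spline system.
#' @return Object of the same class with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad, lambda = 1e-5) {
  if (length(bad) == 0) return(rec)
  is_epochs <- inherits(rec, "epoch_set")
  dat <- flat_channels(rec)
  ch <- rec$channels
  abort_if(!all(c("x", "y", "z") %in% names(ch)),
           "channel positions (x, y, z) are required for interpolation")
  pos <- as.matrix(ch[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  good <- setdiff(seq_len(nrow(pos)), bad)
  abort_if(length(good) < 4, "need at least 4 good channels")
  cosang <- pmin(pmax(tcrossprod(pos), -1), 1)
  G <- spline_g(cosang[good, good, drop = FALSE])
  ng <- length(good)
  A <- rbind(cbind(G + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(dat[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  C <- sol[seq_len(ng), , drop = FALSE]
  d <- sol[ng + 1, ]
  Gb <- spline_g(cosang[bad, good, drop = FALSE])
  dat[bad, ] <- Gb %*% C + matrix(d, length(bad), ncol(dat), byrow = TRUE)
  if (is_epochs) {
    dm <- dim(rec$epochs)
    rec$epochs <- aperm(array(dat, c(dm[2], dm[3], dm[1])), c(3, 1, 2))
  } else {
    rec$data <- dat
  }
  rec
}

#' Cut a recording into fixed-length epochs and reject by amplitude
#'
#' Non-overlapping consecutive epochs from the start of the recording;
#' epochs containing any sample outside `[-limit, +limit]` are dropped
#' with reason code `"amplitude"`. The retention fraction is recorded.
#'
#' @param rec A [sensor_recording()].
#' @param length Epoch length in seconds (default 2).
#' @param limit Absolute amplitude bound in microvolts (default 100).
#' @return An [epoch_set()]; attribute `retention` gives the kept fraction.
#' @export
epoch_and_reject <- function(rec, length = 2, limit = 100) {
  spe <- round(length * rec$rate)
  n_ep <- floor(ncol(rec$data) / spe)
  abort_if(n_ep < 1, "recording shorter than one epoch")
  keep <- logical(n_ep)
  log <- character(n_ep)
  arr <- array(NA_real_, c(n_ep, nrow(rec$data), spe))
  for (e in seq_len(n_ep)) {
    seg <- rec$data[, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
    arr[e, , ] <- seg
    if (max(abs(seg)) > limit) {
      keep[e] <- FALSE
      log[e] <- "amplitude"
    } else {
      keep[e] <- TRUE
      log[e] <- ""
    }
  }
  abort_if(!any(keep), "no clean data: all epochs rejected")
  es <- epoch_set(arr[keep, , , drop = FALSE], rec$rate, length, keep, log,
                  channels = rec$channels,
                  onsets = (which(keep) - 1) * length)
  attr(es, "retention") <- mean(keep)
  es
}

#' Common average reference
#'
#' Subtracts the across-channel mean at every sample, so the spatial mean
#' of the output is zero. Idempotent.
#'
#' @param x An [epoch_set()] or [sensor_recording()] with >= 2 channels.
#' @return Re-referenced object of the same class.
#' @export
common_average_reference <- function(x) {
  if (inherits(x, "epoch_set")) {
    abort_if(dim(x$epochs)[2] < 2, "need at least 2 channels")
    for (e in seq_len(dim(x$epochs)[1])) {
      seg <- x$epochs[e, , ]
      x$epochs[e, , ] <- seg - matrix(colMeans(seg), nrow(seg), ncol(seg),
                                      byrow = TRUE)
    }
  } else if (inherits(x, "sensor_recording")) {
    abort_if(nrow(x$data) < 2, "need at least 2 channels")
    x$data <- sweep(x$data, 2, colMeans(x$data))
  } else {
    stop("common_average_reference expects an epoch_set or sensor_recording")
  }
  x
}

#' Convert raw fNIRS intensity to optical density
#'
#' `OD(t) = -log10(I(t) / I0)` with `I0` the channel's temporal-mean
#' baseline taken in the log domain (geometric mean), so that zero-mean
#' concentration changes are recovered exactly by the Beer-Lambert
#' inversion.
#'
#' @param rec A [sensor_recording()] with strictly positive intensities.
#' @return Recording of optical densities (same channel table).
#' @export
intensity_to_od <- function(rec) {
  bad <- which(rec$data <= 0, arr.ind = TRUE)
  abort_if(nrow(bad) > 0,
           "non-positive intensity at channel %d, sample %d",
           bad[1, 1], bad[1, 2])
  lx <- log10(rec$data)
  rec$data <- -(lx - rowMeans(lx))
  rec$modality <- "fnirs"
  rec
}

## One channel of temporal derivative distribution repair: robust
## (Tukey biweight, c = 4.685) reweighting of the temporal derivative,
## reintegration, mean restored.
tddr_channel <- function(y, tune = 4.685, tol = 1e-6, max_iter = 50) {
  dy <- diff(y)
  if (all(dy == 0)) return(y)
  mu <- 0
  w <- rep(1, length(dy))
  for (iter in seq_len(max_iter)) {
    dev <- dy - mu
    s <- 1.4826 * stats::median(abs(dev))
    if (s < .Machine$double.eps) break
    u <- dev / (tune * s)
    w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    mu_new <- sum(w_new * dy) / max(sum(w_new), .Machine$double.eps)
    delta <- max(abs(w_new - w))
    w <- w_new
    mu <- mu_new
    if (delta < tol) break
  }
  if (iter == max_iter) {
    warning("motion_correct: reweighting did not converge; returning best iterate")
  }
  out <- cumsum(c(0, w * (dy - mu)))
  out + mean(y) - mean(out)
}

#' Motion artifact repair by temporal-derivative reweighting
#'
#' Iteratively reweights the temporal derivative of each optical-density
#' channel with Tukey's biweight (tuning constant 4.685, scale from the
#' median absolute deviation), reintegrates, and restores the channel mean.
#' Abrupt steps and spikes are suppressed while slow hemodynamics pass
#' through nearly unchanged.
#'
#' @param od A [sensor_recording()] of optical densities.
#' @return Repaired recording.
#' @export
motion_correct <- function(od) {
  od$data <- t(apply(od$data, 1, tddr_channel))
  od
}

#' Zero-phase fNIRS band-pass (0.01-0.1 Hz, order-3 Butterworth)
#'
#' @param od A [sensor_recording()] of optical densities (or hemoglobin).
#' @param lo,hi Band edges in Hz.
#' @return Filtered recording. Warns when the record is shorter than 300 s.
#' @export
fnirs_bandpass <- function(od, lo = 0.01, hi = 0.1) {
  abort_if(hi >= od$rate / 2, "upper edge %g Hz >= Nyquist", hi)
  if (ncol(od$data) / od$rate < 300) {
    warning("record shorter than 300 s; band edge at 0.01 Hz is poorly resolved")
  }
  bp <- signal::butter(3, c(lo, hi) / (od$rate / 2), type = "pass")
  od$data <- filtfilt_rows(od$data, bp)
  od
}

#' Modified Beer-Lambert inversion: optical density to hemoglobin
#'
#' Pairs the two wavelengths of each optical channel and solves the 2x2
#' extinction system for (dHbO, dHbR). Exact linear inverse of
#' [hemodynamics_to_raw_intensity()] composed with [intensity_to_od()].
#'
#' @param od A [sensor_recording()] of optical densities whose channel
#'   table has `wavelength`, `source`, `detector` (and optionally `roi`).
#' @param dpf Differential pathlength factors named by wavelength.
#' @param distance Source-detector separation in cm (default 3.0).
#' @return List with `hbo` and `hbr` [sensor_recording()]s (mmol/L,
#'   modality "hb"), one row per optical channel.
#' @export
mbll_invert <- function(od, dpf = c("730" = 6, "850" = 6), distance = 3.0) {
  ch <- od$channels
  abort_if(!all(c("wavelength", "source", "detector") %in% names(ch)),
           "channel table must have wavelength, source, detector")
  wls <- sort(unique(ch$wavelength))
  abort_if(length(wls) != 2, "exactly two distinct wavelengths required")
  eps <- extinction_coefficients()
  abort_if(!all(as.character(wls) %in% rownames(eps)),
           "no extinction coefficients for wavelengths %s",
           paste(wls, collapse = ", "))
  E <- eps[as.character(wls), , drop = FALSE] *
    (distance * unname(dpf[as.character(wls)]))
  abort_if(abs(det(E)) < 1e-12, "extinction system is singular")
  key <- paste(ch$source, ch$detector)
  i1 <- which(ch$wavelength == wls[1])
  i2 <- which(ch$wavelength == wls[2])
  i2 <- i2[match(key[i1], key[i2])]
  abort_if(anyNA(i2), "both wavelengths must be present for every channel pair")
  Einv <- solve(E)
  hb1 <- Einv[1, 1] * od$data[i1, , drop = FALSE] +
    Einv[1, 2] * od$data[i2, , drop = FALSE]
  hb2 <- Einv[2, 1] * od$data[i1, , drop = FALSE] +
    Einv[2, 2] * od$data[i2, , drop = FALSE]
  keep <- c("name", "source", "detector", intersect("roi", names(ch)))
  tab <- ch[i1, keep, drop = FALSE]
  tab$name <- sub(" ?[0-9.]+nm$", "", tab$name)
  list(hbo = sensor_recording(hb1, od$rate, tab, od$annotations, "hb"),
       hbr = sensor_recording(hb2, od$rate, tab, od$annotations, "hb"))
}

#' Resample hemoglobin series onto EEG epoch timestamps
#'
#' Linear interpolation of each hemoglobin channel at the EEG epoch-center
#' timestamps. Timestamps outside the fNIRS time range are marked missing,
#' never extrapolated.
#'
#' @param hb A [sensor_recording()] or [roi_timeseries()] (channels/ROIs x
#'   samples) at the fNIRS rate, starting at time 0.
#' @param epochs An [epoch_set()] with `onsets`.
#' @return List: `values` (channels x epochs, NA where missing),
#'   `timestamps` (epoch centers, s), `missing` (logical).
#' @export
align_modalities <- function(hb, epochs) {
  x <- if (inherits(hb, "sensor_recording") || inherits(hb, "roi_timeseries"))
    hb$data else stop("hb must be a sensor_recording or roi_timeseries")
  abort_if(is.null(epochs$onsets), "epoch set carries no onset timeline")
  t_hb <- (seq_len(ncol(x)) - 1) / hb$rate
  t_ep <- epochs$onsets + epochs$epoch_length / 2
  abort_if(min(t_ep) > max(t_hb) || max(t_ep) < min(t_hb),
           "fNIRS and EEG epoch timelines do not overlap")
  vals <- t(apply(x, 1, function(row) {
    stats::approx(t_hb, row, xout = t_ep, rule = 1)$y
  }))
  list(values = vals, timestamps = t_ep, missing = is.na(vals[1, ]))
}
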