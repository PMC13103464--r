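## S3 containers for raw and conditioned data. Kept deliberately plain:
## lists with a data matrix (channels x samples), a sampling rate, a channel
## table and an annotation table, in the style of eegkit / signal-processing
## packages rather than a heavyweight class hierarchy.

#' Construct a sensor recording
#'
#' @param data Numeric matrix, channels x samples. EEG amplitudes are in
#'   microvolts; fNIRS raw intensities in detector counts; hemoglobin series
#'   in mmol/L.
#' @param rate Sampling rate in Hz.
#' @param channels Data.frame describing the rows of `data`; must contain a
#'   `name` column. For EEG, `x`, `y`, `z` unit-sphere positions; for fNIRS,
#'   `wavelength` (nm), `source`, `detector`.
#' @param annotations Data.frame with columns `onset` (s), `duration` (s),
#'   `label` (e.g. phase markers `pre`/`on`/`post`), or NULL.
#' @param modality One of "eeg", "fnirs", "hb".
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, rate, channels = NULL, annotations = NULL,
                             modality = c("eeg", "fnirs", "hb")) {
  modality <- match.arg(modality)
  check_matrix(data)
  abort_if(!is.numeric(rate) || length(rate) != 1 || rate <= 0,
           "rate must be a single positive number")
  if (is.null(channels)) {
    channels <- data.frame(name = sprintf("ch%02d", seq_len(nrow(data))),
                           stringsAsFactors = FALSE)
  }
  abort_if(nrow(channels) != nrow(data),
           "channel table has %d rows but data has %d channels",
           nrow(channels), nrow(data))
  if (is.null(annotations)) {
    annotations <- data.frame(onset = numeric(0), duration = numeric(0),
                              label = character(0), stringsAsFactors = FALSE)
  }
  structure(list(data = data, rate = rate, channels = channels,
                 annotations = annotations, modality = modality),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$modality, nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate, nrow(x$annotations)))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param rec A `sensor_recording`.
#' @return `n_samples`: integer; `duration`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$data) / rec$rate

#' Construct an epoch set
#'
#' @param epochs 3-d array, epochs x channels x samples.
#' @param rate Sampling rate (Hz).
#' @param epoch_length Epoch length in seconds.
#' @param kept_mask Logical vector over the original consecutive epochs.
#' @param rejection_log Character vector of per-epoch reason codes ("" kept).
#' @param channels Channel table carried over from the recording.
#' @param onsets Numeric vector: onset (s) of each original epoch.
#' @return An object of class `epoch_set` containing only the kept epochs.
#' @export
epoch_set <- function(epochs, rate, epoch_length, kept_mask, rejection_log,
                      channels = NULL, onsets = NULL) {
  abort_if(length(dim(epochs)) != 3, "epochs must be a 3-d array")
  structure(list(epochs = epochs, rate = rate, epoch_length = epoch_length,
                 kept_mask = kept_mask, rejection_log = rejection_log,
                 channels = channels, onsets = onsets),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d kept / %d total epochs of %g s (%d channels @ %g Hz)\n",
              dim(x$epochs)[1], length(x$kept_mask), x$epoch_length,
              dim(x$epochs)[2], x$rate))
  invisible(x)
}

#' Construct a ROI time-series container
#'
#' @param data Numeric matrix, ROIs x samples (continuous) or a 3-d array
#'   epochs x ROIs x samples (epoched).
#' @param rate Sampling rate in Hz.
#' @param roi_labels Character vector of ROI labels (rows of `data`).
#' @param meta Named list of tags (subject, phase, band, chromophore, ...).
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, rate, roi_labels = NULL, meta = list()) {
  nd <- length(dim(data))
  abort_if(!nd %in% c(2, 3), "data must be a matrix or a 3-d array")
  n_roi <- if (nd == 2) nrow(data) else dim(data)[2]
  if (is.null(roi_labels)) roi_labels <- sprintf("roi%02d", seq_len(n_roi))
  abort_if(length(roi_labels) != n_roi, "roi_labels length mismatch")
  structure(list(data = data, rate = rate, roi_labels = roi_labels,
                 meta = meta),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  d <- dim(x$data)
  if (length(d) == 2) {
    cat(sprintf("<roi_timeseries> %d ROIs x %d samples @ %g Hz\n",
                d[1], d[2], x$rate))
  } else {
    cat(sprintf("<roi_timeseries> %d epochs x %d ROIs x %d samples @ %g Hz\n",
                d[1], d[2], d[3], x$rate))
  }
  invisible(x)
}

#' Construct a connectivity matrix
#'
#' @param values Symmetric numeric matrix (ROIs x ROIs).
#' @param modality One of `plv-delta` ... `plv-gamma`, `hbo-r`, `hbr-r`,
#'   `hbo-z`, `hbr-z`.
#' @param roi_labels Row/column labels.
#' @param meta Named list of tags (subject, phase, stim_frequency).
#' @return Object of class `connectivity_matrix` (the matrix with attributes).
#' @export
connectivity_matrix <- function(values, modality, roi_labels = NULL,
                                meta = list()) {
  check_matrix(values)
  abort_if(!is_symmetric(values, 1e-8), "connectivity values must be symmetric")
  if (startsWith(modality, "plv")) {
    abort_if(any(values < -1e-12 | values > 1 + 1e-12),
             "PLV entries must lie in [0, 1]")
  }
  if (!is.null(roi_labels)) dimnames(values) <- list(roi_labels, roi_labels)
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            modality = modality, meta = meta)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d x %d\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  invisible(x)
}
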