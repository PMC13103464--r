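## File interchange. EEG recordings go to/from EDF (16-bit European Data
## Format, one 1-s data record per second); annotations travel in a
## BIDS-style events TSV sidecar; fNIRS and intermediate arrays use a plain
## columnar TSV bundle (data + channel table + events + JSON metadata).

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' Write a recording to EDF
#'
#' 16-bit EDF with 1-second data records; the final partial record is
#' padded with each channel's last value (the true sample count is
#' recoverable from the events sidecar or the caller's bookkeeping).
#' Annotations are written to `<path>.events.tsv` via [write_events()].
#'
#' @param rec A [sensor_recording()] with an integer sampling rate.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  abort_if(rec$rate != round(rec$rate), "EDF writer requires an integer rate")
  x <- rec$data
  ns <- nrow(x)
  spr <- as.integer(rec$rate)
  n_rec <- as.integer(ceiling(ncol(x) / spr))
  total <- n_rec * spr
  if (total > ncol(x)) {
    x <- cbind(x, x[, rep(ncol(x), total - ncol(x)), drop = FALSE])
  }
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_ascii("0", 8))
  wr(pad_ascii("X X X X", 80))
  wr(pad_ascii(sprintf("Startdate 01-JAN-2000 X X %s", rec$modality), 80))
  wr(pad_ascii("01.01.00", 8))
  wr(pad_ascii("00.00.00", 8))
  wr(pad_ascii(256 + ns * 256, 8))
  wr(pad_ascii("", 44))
  wr(pad_ascii(n_rec, 8))
  wr(pad_ascii("1", 8))
  wr(pad_ascii(ns, 4))
  labels <- rec$channels$name
  wr(paste(vapply(labels, pad_ascii, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * ns))                      # transducer
  unit <- if (rec$modality == "eeg") "uV" else "counts"
  wr(paste(rep(pad_ascii(unit, 8), ns), collapse = ""))
  wr(paste(vapply(sprintf("%.6g", pmin_), pad_ascii, "", width = 8), collapse = ""))
  wr(paste(vapply(sprintf("%.6g", pmax_), pad_ascii, "", width = 8), collapse = ""))
  wr(paste(rep(pad_ascii(dmin, 8), ns), collapse = ""))
  wr(paste(rep(pad_ascii(dmax, 8), ns), collapse = ""))
  wr(strrep(" ", 80 * ns))                      # prefiltering
  wr(paste(rep(pad_ascii(spr, 8), ns), collapse = ""))
  wr(strrep(" ", 32 * ns))
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- x[ch, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - pmin_[ch]) * scale[ch] + dmin))
      dig <- pmin.int(pmax.int(dig, as.integer(dmin)), as.integer(dmax))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  if (nrow(rec$annotations) > 0) {
    write_events(rec$annotations, paste0(path, ".events.tsv"))
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the 16-bit EDF written by [write_edf()] (and plain continuous
#' EDF generally). If `<path>.events.tsv` exists, its rows become the
#' recording's annotations.
#'
#' @param path EDF file path.
#' @param modality Modality tag for the result.
#' @return A [sensor_recording()].
#' @export
read_edf <- function(path, modality = "eeg") {
  abort_if(!file.exists(path), "file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  abort_if(version != "0", "not an EDF file (version field '%s' at byte 0)",
           version)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  abort_if(is.na(ns) || ns < 1, "malformed EDF: bad signal count field")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  replicate(ns, rd(80))
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  replicate(ns, rd(80))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  replicate(ns, rd(32))
  abort_if(length(unique(spr)) != 1,
           "mixed per-signal rates are not supported")
  seek(con, header_bytes)
  x <- matrix(NA_real_, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      abort_if(length(dig) < spr[ch],
               "truncated EDF data at record %d, signal %d", r, ch)
      x[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch]) +
        pmin_[ch]
    }
  }
  ev_path <- paste0(path, ".events.tsv")
  ann <- if (file.exists(ev_path)) read_events(ev_path) else NULL
  sensor_recording(x, spr[1] / rec_dur,
                   data.frame(name = labels, unit = units,
                              stringsAsFactors = FALSE),
                   ann, modality = modality)
}

#' Write / read a BIDS-style events table
#'
#' Columns `onset` (s), `duration` (s), `trial_type`.
#'
#' @param annotations data.frame with `onset`, `duration`, `label`
#'   (or `trial_type`).
#' @param path Output TSV path.
#' @return `path` (write) / annotations data.frame with `onset`,
#'   `duration`, `label` (read).
#' @export
write_events <- function(annotations, path) {
  df <- data.frame(onset = annotations$onset,
                   duration = annotations$duration,
                   trial_type = if (!is.null(annotations$label))
                     annotations$label else annotations$trial_type)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(onset = df$onset, duration = df$duration,
             label = df$trial_type, stringsAsFactors = FALSE)
}

#' Write / read a columnar TSV bundle
#'
#' A directory with `data.tsv` (samples x channels, named columns),
#' `channels.tsv`, `events.tsv` and `meta.json` (rate, modality). The
#' lossless plain-text interchange format for fNIRS and intermediate
#' arrays.
#'
#' @param rec A [sensor_recording()].
#' @param dir Bundle directory (created if needed).
#' @return `dir` (write) / a [sensor_recording()] (read).
#' @export
write_tsv_bundle <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- t(rec$data)
  colnames(m) <- rec$channels$name
  utils::write.table(m, file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(rec$channels, file.path(dir, "channels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_events(rec$annotations, file.path(dir, "events.tsv"))
  jsonlite::write_json(list(rate = rec$rate, modality = rec$modality),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_tsv_bundle
#' @export
read_tsv_bundle <- function(dir) {
  need <- file.path(dir, c("data.tsv", "channels.tsv", "meta.json"))
  missing <- need[!file.exists(need)]
  abort_if(length(missing) > 0, "malformed bundle: missing %s",
           paste(basename(missing), collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  data <- t(as.matrix(utils::read.delim(file.path(dir, "data.tsv"),
                                        check.names = FALSE)))
  channels <- utils::read.delim(file.path(dir, "channels.tsv"),
                                stringsAsFactors = FALSE)
  ev_path <- file.path(dir, "events.tsv")
  ann <- if (file.exists(ev_path)) read_events(ev_path) else NULL
  sensor_recording(data, meta$rate, channels, ann, modality = meta$modality)
}

#' Load a recording from disk
#'
#' @param path File (EDF) or directory (TSV bundle) path.
#' @param format "edf" or "tsv-bundle".
#' @param modality Modality tag.
#' @return A [sensor_recording()] with annotations mapped to phase labels
#'   where an events sidecar is present.
#' @export
load_recording <- function(path, format = c("edf", "tsv-bundle"),
                           modality = "eeg") {
  format <- match.arg(format)
  switch(format,
         "edf" = read_edf(path, modality),
         "tsv-bundle" = read_tsv_bundle(path))
}
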