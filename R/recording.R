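#' Construct an EEG recording object
#'
#' The raw-signal container used throughout the package: a channels-by-samples
#' numeric matrix (in microvolts) together with the sampling rate and the
#' ordered 10-10 electrode labels.
#'
#' @param data numeric matrix, channels x samples, in microvolts. All values
#'   must be finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of unique electrode names, one per row of
#'   `data`.
#' @param meta optional named list of free-form provenance (source file,
#'   generator settings, filter history, ...).
#' @return an object of class `eeg_recording` with elements `data`, `fs`,
#'   `labels`, `meta`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 1000), 2), fs = 500,
#'                      labels = c("C3", "C4"))
#' rec
#' @export
eeg_recording <- function(data, fs, labels, meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) {
    stop_rwenet("an EEG recording needs at least 2 channels", "rwenet_format_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_rwenet("missing or invalid field 'fs': sampling rate must be a positive number",
                "rwenet_format_error")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(data) || anyDuplicated(labels) || anyNA(labels)) {
    stop_rwenet("missing or invalid field 'labels': need one unique label per channel",
                "rwenet_format_error")
  }
  if (!all(is.finite(data))) {
    stop_rwenet("recording data contain non-finite samples", "rwenet_format_error")
  }
  structure(list(data = data, fs = fs, labels = labels, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  labels:", paste(utils::head(x$labels, 8), collapse = " "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Two on-disk formats are supported: European Data Format (`.edf`, 16-bit
#' clinical exchange format) and a plain numeric matrix (whitespace- or
#' comma-delimited, channels in rows) accompanied by a JSON or YAML sidecar
#' holding `fs` and `labels`.
#'
#' @param path path to the `.edf` or matrix file. For the matrix format the
#'   sidecar is looked up as `<path>.json` / `<path>.yaml` / `<path>.yml` or
#'   the same names with the matrix extension replaced.
#' @param format `"auto"` (by extension), `"edf"`, or `"matrix"`.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_rwenet(sprintf("cannot read '%s': no such file", path), "rwenet_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") {
    return(read_edf(path))
  }
  data <- tryCatch(
    as.matrix(utils::read.table(path, header = FALSE, sep = "",
                                colClasses = "numeric")),
    error = function(e) {
      tryCatch(as.matrix(utils::read.table(path, header = FALSE, sep = ",",
                                           colClasses = "numeric")),
               error = function(e2) stop_rwenet(
                 sprintf("cannot parse '%s' as a numeric matrix", path),
                 "rwenet_io_error"))
    })
  side <- find_sidecar(path)
  if (is.null(side)) {
    stop_rwenet(sprintf("no JSON/YAML sidecar found for '%s'", path),
                "rwenet_format_error")
  }
  meta <- if (grepl("\\.json$", side, ignore.case = TRUE)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(side)
  }
  if (is.null(meta$fs)) {
    stop_rwenet(sprintf("sidecar '%s' is missing field 'fs'", side),
                "rwenet_format_error")
  }
  if (is.null(meta$labels)) {
    stop_rwenet(sprintf("sidecar '%s' is missing field 'labels'", side),
                "rwenet_format_error")
  }
  eeg_recording(data, fs = meta$fs, labels = unlist(meta$labels),
                meta = list(source = path, sidecar = side))
}

find_sidecar <- function(path) {
  stem <- sub("\\.[^.]+$", "", path)
  cand <- c(paste0(path, c(".json", ".yaml", ".yml")),
            paste0(stem, c(".json", ".yaml", ".yml")))
  cand <- cand[file.exists(cand)]
  if (length(cand)) cand[[1]] else NULL
}

#' Temporal filtering of a recording
#'
#' Channel means are removed, then a Butterworth high-pass and a Butterworth
#' band-stop (notch) filter are applied forward and backward (zero phase, no
#' group delay) to every channel.
#'
#' @param rec an [eeg_recording()].
#' @param hp_hz high-pass cut-off in Hz.
#' @param notch_hz centre of the notch in Hz.
#' @param order Butterworth order of both filters.
#' @param notch_halfwidth half-width of the stop band in Hz, so the notch
#'   rejects `notch_hz +/- notch_halfwidth`.
#' @return a filtered `eeg_recording` of the same shape; the filter settings
#'   are appended to `meta$filter`.
#' @export
filter_recording <- function(rec, hp_hz = 1, notch_hz = 50, order = 3,
                             notch_halfwidth = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(hp_hz > 0 && hp_hz < notch_hz && notch_hz < nyq)) {
    stop_rwenet(sprintf(
      "need 0 < hp_hz < notch_hz < fs/2; got hp=%g, notch=%g, Nyquist=%g",
      hp_hz, notch_hz, nyq), "rwenet_parameter_error")
  }
  lo <- max(notch_hz - notch_halfwidth, hp_hz)
  hi <- min(notch_hz + notch_halfwidth, nyq * 0.999)
  bf_hp <- signal::butter(order, hp_hz / nyq, type = "high")
  bf_no <- signal::butter(order, c(lo, hi) / nyq, type = "stop")
  out <- rec$data - rowMeans(rec$data)
  for (i in seq_len(nrow(out))) {
    y <- signal::filtfilt(bf_hp, out[i, ])
    out[i, ] <- signal::filtfilt(bf_no, y)
  }
  meta <- rec$meta
  meta$filter <- c(meta$filter,
                   list(list(hp_hz = hp_hz, notch_hz = notch_hz, order = order,
                             notch_halfwidth = notch_halfwidth,
                             zero_phase = TRUE)))
  eeg_recording(out, rec$fs, rec$labels, meta)
}

#' Randomized selection of artifact-free epochs
#'
#' The recording is cut into non-overlapping candidate windows of
#' `epoch_seconds` and `n_epochs` of them are drawn uniformly without
#' replacement.  Randomized (rather than sequential) selection avoids
#' systematic sampling bias along the recording; drawing without replacement
#' keeps the epochs pairwise disjoint so no stretch of data is double-counted
#' in the downstream synchronization average.
#'
#' @param rec an [eeg_recording()].
#' @param n_epochs number of epochs to select.
#' @param epoch_seconds epoch duration in seconds.
#' @param seed integer seed; identical seeds give identical selections.
#' @param exclude optional two-column matrix of bad segments
#'   (start sample, end sample; 1-based, inclusive); any candidate window
#'   overlapping a bad segment is removed before sampling.
#' @return a list of `eeg_epoch` objects, each holding `data`, `fs`, and the
#'   0-based `start_sample` offset into the parent recording.
#' @export
select_epochs <- function(rec, n_epochs = 75, epoch_seconds = 20, seed = NULL,
                          exclude = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_seconds * rec$fs)
  n_samples <- ncol(rec$data)
  slots <- floor(n_samples / len)
  starts0 <- (seq_len(slots) - 1L) * len     # 0-based
  if (!is.null(exclude)) {
    exclude <- matrix(as.numeric(exclude), ncol = 2)
    keep <- vapply(starts0, function(s) {
      !any(s + 1 <= exclude[, 2] & s + len >= exclude[, 1])
    }, logical(1))
    starts0 <- starts0[keep]
  }
  if (length(starts0) < n_epochs) {
    stop_rwenet(sprintf(
      "recording too short: %d epochs of %g s requested (%.0f s needed) but only %d usable windows (%.0f s available)",
      n_epochs, epoch_seconds, n_epochs * epoch_seconds, length(starts0),
      n_samples / rec$fs), "rwenet_data_error")
  }
  picked <- if (length(starts0) == 1L) starts0 else
    with_seed(seed, sort(sample(starts0, n_epochs)))
  lapply(picked, function(s) {
    structure(list(data = rec$data[, (s + 1):(s + len), drop = FALSE],
                   fs = rec$fs, labels = rec$labels, start_sample = s),
              class = "eeg_epoch")
  })
}
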