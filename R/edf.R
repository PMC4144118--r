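# Minimal European Data Format (EDF) reader/writer.
# EDF is a fixed-layout 16-bit integer exchange format: a 256-byte ASCII
# header, 256 bytes per signal of signal headers, then data records of
# little-endian int16 samples scaled linearly between the digital and
# physical ranges declared in the header.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the full 16-bit digital range, so the
#' round trip is exact up to the format's quantization step
#' (physical range / 65534).
#'
#' @param rec an [eeg_recording()]; `fs * record_seconds` must be an integer.
#' @param path output file path.
#' @param record_seconds duration of one EDF data record; trailing samples
#'   that do not fill a whole record are dropped.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_seconds = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  spr <- rec$fs * record_seconds
  if (abs(spr - round(spr)) > 1e-9) {
    stop_rwenet("fs * record_seconds must be an integer", "rwenet_parameter_error")
  }
  spr <- as.integer(round(spr))
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1) stop_rwenet("recording shorter than one data record", "rwenet_data_error")

  pmax_ <- apply(rec$data, 1, function(x) max(abs(x), 1e-6))
  pmin_ <- -pmax_
  dmin <- -32767L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.01", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(record_seconds), 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$labels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(sprintf("%.6g", pmin_), edf_pad, "", width = 8),
    vapply(sprintf("%.6g", pmax_), edf_pad, "", width = 8),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(spr, 8), ns),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((rec$data[ch, idx] - pmin_[ch]) * scale[ch]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    out <- readChar(con, n, useBytes = TRUE)
    if (length(out) == 0 || nchar(out, type = "bytes") < n) {
      stop_rwenet(sprintf("'%s': truncated EDF header", path), "rwenet_io_error")
    }
    trimws(out)
  }
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)           # patient, recording, date, time
  rd(8); rd(44)                          # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    stop_rwenet(sprintf("'%s': malformed EDF header (missing fs or signal count)", path),
                "rwenet_format_error")
  }
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdn(16)
  rdn(80); rdn(8)
  pmin_ <- as.numeric(rdn(8)); pmax_ <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (length(unique(spr)) != 1L) {
    stop_rwenet(sprintf("'%s': mixed per-signal sampling rates are not supported", path),
                "rwenet_format_error")
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      if (length(dig) < spr[ch]) {
        stop_rwenet(sprintf("'%s': truncated EDF data record", path), "rwenet_io_error")
      }
      data[ch, idx] <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  eeg_recording(data, fs = fs, labels = labels, meta = list(source = path))
}
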