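# Minimal European Data Format (EDF) I/O.
# Implements the continuous-recording subset used here: identical sampling
# rate on all signals, 1-second data records, 16-bit little-endian samples.
# No R EDF reader is declared as a dependency, so the format is handled
# directly; the writer/reader pair is round-trip tested.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  # numeric header field in at most `width` ASCII characters
  s <- formatC(x, format = "g", digits = width - 2, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  if (nchar(s) > width) stop("cannot format ", x, " in ", width, " chars")
  edf_pad(s, width)
}

#' Write an EEG recording to an EDF file
#'
#' Samples are scaled per channel to the 16-bit digital range; physical units
#' are microvolts. The sampling rate must be a positive integer and the data
#' are truncated to a whole number of 1-second records.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param patient Patient identification string.
#' @param recording_id Recording identification string.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "synthetic") {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$rate
  if (rate != round(rate)) stop("write_edf requires an integer sampling rate")
  ns <- length(rec$channels)
  n_rec <- floor(nrow(rec$data) / rate)
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  used <- n_rec * rate
  if (used < nrow(rec$data))
    warning(sprintf("truncating %d trailing samples to whole records",
                    nrow(rec$data) - used))
  x <- rec$data[seq_len(used), , drop = FALSE]

  pmin <- apply(x, 2, min); pmax <- apply(x, 2, max)
  # symmetric physical range with headroom; degenerate channels get +-1
  half <- pmax(pmax(abs(pmin), abs(pmax)) * 1.01, 1)
  pmin <- -half; pmax <- half
  dmin <- -32767; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(vapply(rec$channels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(rate, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  ), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- matrix(0L, nrow = used, ncol = ns)
  for (j in seq_len(ns))
    dig[, j] <- as.integer(round((x[, j] - pmin[j]) * scale[j] + dmin))
  # record-major layout: for each 1-s record, all samples of signal 1, then 2, ...
  out <- integer(used * ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (j in seq_len(ns)) {
      out[(pos + 1L):(pos + rate)] <- dig[idx, j]
      pos <- pos + as.integer(rate)
    }
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Supports continuous EDF files in which every signal shares one sampling
#' rate, as produced by [write_edf()].
#'
#' @param path Path to an EDF file.
#' @return An [eeg_recording()] in physical units (microvolts).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes (implied by ns)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # transducer
  vapply(seq_len(ns), function(i) rd(8), "")    # dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1)
    stop("read_edf supports a single shared sampling rate only")
  rate <- spr[1] / rec_dur

  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  data <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (j in seq_len(ns)) {
      data[idx, j] <- raw[(pos + 1L):(pos + spr[j])]
      pos <- pos + spr[j]
    }
  }
  for (j in seq_len(ns)) {
    g <- (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
    data[, j] <- (data[, j] - dmin[j]) * g + pmin[j]
  }
  eeg_recording(data, rate, labels)
}
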