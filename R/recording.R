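#' Construct an EEG recording object
#'
#' Container for continuous multichannel EEG: a samples x channels numeric
#' matrix in microvolts plus sampling-rate and channel metadata.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param rate Sampling rate in Hz.
#' @param channels Character vector of channel labels (one per column).
#' @param meta Optional named list of free-form metadata.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channels, meta = list()) {
  data <- as.matrix(data)
  if (ncol(data) != length(channels))
    stop("ncol(data) must equal length(channels)")
  if (rate <= 0) stop("rate must be positive")
  colnames(data) <- channels
  structure(
    list(data = data, rate = rate, channels = channels, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), nrow(x$data), x$rate,
              nrow(x$data) / x$rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$rate

#' Restrict a recording to a subset of channels
#' @param rec An `eeg_recording`.
#' @param channels Channel labels to keep, in the requested order.
#' @return The subsetted `eeg_recording`.
#' @export
select_channels <- function(rec, channels) {
  missing <- setdiff(channels, rec$channels)
  if (length(missing) > 0)
    stop("channel(s) not present: ", paste(missing, collapse = ", "))
  eeg_recording(rec$data[, channels, drop = FALSE], rec$rate, channels,
                rec$meta)
}

#' Construct an epoch set
#'
#' Fixed-length, non-overlapping EEG segments stored as a 3-D array
#' `[epoch, sample, channel]`.
#'
#' @param data 3-D numeric array `[epoch, sample, channel]`.
#' @param rate Sampling rate in Hz.
#' @param channels Channel labels.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, rate, channels) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(channels))
  structure(list(data = data, rate = rate, channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d samples x %d channels @ %g Hz\n",
              d[1], d[2], d[3], x$rate))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]
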