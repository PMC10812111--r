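# Resting-state spectral chain: band-pass filter, fixed-length epoching,
# improbability-based epoch rejection, zero-padded log-periodogram and
# individual-alpha-frequency detection.

bandpass_filtfilt <- function(x, rate, band, order = 6) {
  nyq <- rate / 2
  lo <- band[1] / nyq
  hi <- band[2] / nyq
  if (hi >= 1) hi <- 0.999
  x <- x - mean(x)  # remove DC before the (slow-settling) high-pass
  # very low high-pass corners are numerically fragile at high order;
  # cascade a gentle high-pass with a steep low-pass
  hp <- signal::butter(2, lo, type = "high")
  lp <- signal::butter(order, hi, type = "low")
  y <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, y)
}

#' Band-pass filter a recording and cut it into fixed-length epochs
#'
#' Applies a zero-phase Butterworth band-pass to every channel, then splits
#' the recording into non-overlapping consecutive epochs; a trailing
#' remainder shorter than one epoch is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param band Pass band in Hz (default `c(0.1, 40)`).
#' @param epoch_len Epoch length in seconds (default 2).
#' @return An [epoch_set()].
#' @export
filter_and_epoch <- function(rec, band = c(0.1, 40), epoch_len = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(epoch_len * rec$rate)
  n_ep <- floor(nrow(rec$data) / spe)
  if (n_ep < 1) stop("recording shorter than one epoch")
  filt <- apply(rec$data, 2, bandpass_filtfilt, rate = rec$rate, band = band)
  arr <- array(0, dim = c(n_ep, spe, length(rec$channels)))
  for (e in seq_len(n_ep))
    arr[e, , ] <- filt[((e - 1) * spe + 1):(e * spe), , drop = FALSE]
  epoch_set(arr, rec$rate, rec$channels)
}

epoch_improbability <- function(epochs, n_bins = 100) {
  # per epoch x channel: mean negative log probability of the epoch's
  # samples under a per-channel histogram density (add-one smoothed)
  # fitted on all epochs pooled
  d <- dim(epochs$data)
  stat <- matrix(0, nrow = d[1], ncol = d[3])
  for (ch in seq_len(d[3])) {
    x <- epochs$data[, , ch]
    rng <- range(x)
    if (diff(rng) == 0) {
      stat[, ch] <- 0
      next
    }
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(x, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(bin, nbins = n_bins) + 1
    p <- counts / sum(counts)
    nlp <- -log(p)[bin]
    dim(nlp) <- dim(x)
    stat[, ch] <- rowMeans(nlp)
  }
  stat
}

#' Reject improbable epochs (joint-probability test)
#'
#' For every epoch and channel an improbability statistic is computed: the
#' mean negative log probability of the epoch's samples under the channel's
#' empirical amplitude distribution (100-bin histogram with add-one
#' smoothing, fitted over all epochs). An epoch is rejected when any
#' single-channel statistic exceeds that channel's across-epoch mean by
#' more than `k_single` standard deviations, or when the all-channel mean
#' statistic exceeds its mean by more than `k_global` SDs. Rejection is
#' one-sided: only improbable (artifact-like) epochs are removed,
#' unusually typical ones are kept.
#'
#' @param epochs An [epoch_set()] with at least 3 epochs.
#' @param k_single Single-channel threshold in SD units (default 1.7).
#' @param k_global Global threshold in SD units (default 1.7).
#' @return List with `epochs` (survivors), `mask` (logical, `TRUE` =
#'   rejected) and the `statistic` matrix.
#' @export
joint_probability_reject <- function(epochs, k_single = 1.7,
                                     k_global = 1.7) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_epochs(epochs) < 3) stop("need at least 3 epochs")
  stat <- epoch_improbability(epochs)
  zscore <- function(s) {
    sdv <- stats::sd(s)
    if (sdv == 0) return(rep(0, length(s)))
    (s - mean(s)) / sdv
  }
  z_single <- apply(stat, 2, zscore)
  z_global <- zscore(rowMeans(stat))
  reject <- apply(z_single > k_single, 1, any) | z_global > k_global
  if (all(reject))
    stop(sprintf(
      "all epochs rejected at k_single=%g, k_global=%g SD", k_single,
      k_global))
  keep <- epochs$data[!reject, , , drop = FALSE]
  list(epochs = epoch_set(keep, epochs$rate, epochs$channels),
       mask = reject, statistic = stat)
}

#' Averaged log power spectrum of one channel
#'
#' Per-epoch periodograms on a zero-padded FFT grid with exactly the
#' requested frequency resolution, logarithmized and then averaged across
#' epochs.
#'
#' @param epochs An [epoch_set()].
#' @param channel Channel label (default `"Pz"`).
#' @param fmax Upper frequency bound in Hz (default 40).
#' @param resolution Frequency bin spacing in Hz (default 0.05). Must be at
#'   least as fine as the raw resolution `1/epoch_len`.
#' @return An object of class `power_spectrum`: list with `freqs` (Hz),
#'   `log_power` (log10), `n_epochs_averaged`.
#' @export
log_power_spectrum <- function(epochs, channel = "Pz", fmax = 40,
                               resolution = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!channel %in% epochs$channels)
    stop("channel not present: ", channel)
  d <- dim(epochs$data)
  spe <- d[2]
  raw_res <- epochs$rate / spe
  if (resolution > raw_res + 1e-12)
    stop(sprintf("resolution %g Hz coarser than raw resolution %g Hz",
                 resolution, raw_res))
  nfft <- round(epochs$rate / resolution)
  if (abs(nfft * resolution - epochs$rate) > 1e-9)
    stop("rate must be an integer multiple of resolution")
  ch <- match(channel, epochs$channels)
  half <- floor(nfft / 2) + 1
  freqs <- (seq_len(half) - 1) * resolution
  keep <- freqs <= fmax + 1e-12
  acc <- numeric(sum(keep))
  floor_p <- 1e-12
  for (e in seq_len(d[1])) {
    x <- c(epochs$data[e, , ch], numeric(nfft - spe))
    pxx <- Mod(stats::fft(x)[seq_len(half)])^2 / (spe * epochs$rate)
    acc <- acc + log10(pmax(pxx[keep], floor_p))
  }
  structure(list(freqs = freqs[keep], log_power = acc / d[1],
                 n_epochs_averaged = d[1]),
            class = "power_spectrum")
}

#' Detect the individual alpha frequency
#'
#' Returns the frequency of maximal averaged log power within a closed
#' search band; ties are broken toward the lower frequency (a completely
#' flat band returns its lower edge with a warning).
#'
#' @param spectrum A [log_power_spectrum()] result.
#' @param band Search band in Hz (default `c(7, 13)`).
#' @return An object of class `iaf_result`: list with `iaf` (Hz),
#'   `search_band`, `peak_log_power`.
#' @export
detect_iaf <- function(spectrum, band = c(7, 13)) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sel <- which(spectrum$freqs >= band[1] - 1e-12 &
                 spectrum$freqs <= band[2] + 1e-12)
  if (length(sel) == 0) stop("empty search band")
  lp <- spectrum$log_power[sel]
  if (diff(range(lp)) == 0)
    warning("flat spectrum in search band; returning its lower edge")
  i <- sel[which.max(lp)]  # which.max takes the first (lowest-frequency) tie
  structure(list(iaf = spectrum$freqs[i], search_band = band,
                 peak_log_power = spectrum$log_power[i]),
            class = "iaf_result")
}

#' Individual alpha frequency from a resting recording
#'
#' The on-site analysis chain: blink removal on the full montage, then the
#' spectral channel (default Pz) alone is band-pass filtered, epoched into
#' 2 s segments, cleaned by the single-channel joint-probability test, and
#' the IAF is the argmax of the averaged log periodogram in the search
#' band.
#'
#' @param rec A resting [eeg_recording()].
#' @param channel Spectral channel (default `"Pz"`).
#' @param band Search band in Hz (default `c(7, 13)`).
#' @param k_jp Joint-probability threshold in SD units (default 1.7).
#' @param resolution Spectral resolution in Hz (default 0.05).
#' @return An `iaf_result` (see [detect_iaf()]) with an added
#'   `n_epochs_used` field.
#' @export
iaf_from_rest <- function(rec, channel = "Pz", band = c(7, 13),
                          k_jp = 1.7, resolution = 0.05) {
  rec <- remove_blink_artifacts(rec)
  if (channel %in% rec$channels && length(rec$channels) > 1)
    rec <- select_channels(rec, channel)
  epochs <- filter_and_epoch(rec)
  jp <- joint_probability_reject(epochs, k_single = k_jp, k_global = k_jp)
  spec <- log_power_spectrum(jp$epochs, channel = channel,
                             resolution = resolution)
  res <- detect_iaf(spec, band = band)
  res$n_epochs_used <- spec$n_epochs_averaged
  res
}

#' Remove blink artifacts by frontal-reference regression
#'
#' Automated substitute for visual independent-component curation: a blink
#' reference is formed as the 0.5-4 Hz band-passed mean of Fp1 and Fp2 and
#' regressed out of every channel. Because the reference carries no energy
#' at alpha frequencies, alpha activity is untouched by construction.
#'
#' @param rec An [eeg_recording()] containing Fp1 and Fp2.
#' @param ref_band Band of the blink reference in Hz.
#' @return The cleaned [eeg_recording()].
#' @export
remove_blink_artifacts <- function(rec, ref_band = c(0.5, 4)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fp <- intersect(c("Fp1", "Fp2"), rec$channels)
  if (length(fp) == 0) return(rec)
  ref <- rowMeans(rec$data[, fp, drop = FALSE])
  ref <- bandpass_filtfilt(ref, rec$rate, ref_band)
  v <- sum(ref^2)
  if (v == 0) return(rec)
  beta <- as.numeric(crossprod(rec$data, ref)) / v
  rec$data <- rec$data - outer(ref, beta)
  rec
}
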