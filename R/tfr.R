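# Continuous-wavelet alpha power chain: resample/filter/detrend, epoch
# cleaning with amplitude rules and spherical interpolation, Morlet CWT on
# a 69-step log-frequency grid, and condition-level alpha summaries.

#' Cleaning parameters for the wavelet chain
#'
#' @param resample_rate Target rate in Hz (default 250).
#' @param band Band-pass in Hz (default `c(1, 40)`).
#' @param k_jp Joint-probability threshold in SD units (default 2).
#' @param amp_thresh Absolute amplitude threshold in microvolts (default
#'   150).
#' @param bad_epoch_channel_frac Channel exclusion when marked in more than
#'   this fraction of epochs (default 0.15).
#' @param max_bad_channels_per_epoch Epoch rejection when more than this
#'   many channels are marked (default 10).
#' @return An object of class `cleaning_params`.
#' @export
cleaning_params <- function(resample_rate = 250, band = c(1, 40),
                            k_jp = 2, amp_thresh = 150,
                            bad_epoch_channel_frac = 0.15,
                            max_bad_channels_per_epoch = 10) {
  stopifnot(resample_rate > 0, all(band > 0), k_jp > 0, amp_thresh > 0,
            bad_epoch_channel_frac > 0, bad_epoch_channel_frac < 1,
            max_bad_channels_per_epoch > 0)
  structure(list(resample_rate = resample_rate, band = band, k_jp = k_jp,
                 amp_thresh = amp_thresh,
                 bad_epoch_channel_frac = bad_epoch_channel_frac,
                 max_bad_channels_per_epoch = max_bad_channels_per_epoch),
            class = "cleaning_params")
}

#' Resample, band-pass and detrend a continuous recording
#'
#' Anti-aliased resampling to the target rate (polyphase FIR), zero-phase
#' Butterworth band-pass and per-channel linear detrending. Exclusion of the
#' during-stimulation block is a pipeline-level rule: that block is simply
#' never passed through this chain.
#'
#' @param rec An [eeg_recording()] sampled at >= the target rate.
#' @param params A [cleaning_params()].
#' @return The preprocessed [eeg_recording()].
#' @export
preprocess_continuous <- function(rec, params = cleaning_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate < params$resample_rate)
    stop("input rate below target resample rate")
  data <- rec$data
  if (rec$rate != params$resample_rate) {
    r <- rec$rate / params$resample_rate
    if (abs(r - round(r)) > 1e-9)
      stop("rate ratio must be an integer")
    data <- apply(data, 2, function(x)
      signal::decimate(x, round(r), ftype = "fir"))
  }
  data <- apply(data, 2, bandpass_filtfilt, rate = params$resample_rate,
                band = params$band)
  n <- nrow(data)
  t <- seq_len(n)
  tc <- t - mean(t)
  denom <- sum(tc^2)
  slope <- as.numeric(crossprod(data, tc)) / denom
  data <- sweep(data, 2, colMeans(data))
  data <- data - outer(tc, slope)
  eeg_recording(data, params$resample_rate, rec$channels, rec$meta)
}

#' Epoch a continuous recording without filtering
#'
#' @param rec An [eeg_recording()].
#' @param epoch_len Epoch length in seconds (default 2).
#' @return An [epoch_set()].
#' @export
epoch_recording <- function(rec, epoch_len = 2) {
  spe <- round(epoch_len * rec$rate)
  n_ep <- floor(nrow(rec$data) / spe)
  if (n_ep < 1) stop("recording shorter than one epoch")
  arr <- array(0, dim = c(n_ep, spe, length(rec$channels)))
  for (e in seq_len(n_ep))
    arr[e, , ] <- rec$data[((e - 1) * spe + 1):(e * spe), , drop = FALSE]
  epoch_set(arr, rec$rate, rec$channels)
}

#' Artifact cleaning of an epoch set
#'
#' Applies, in order: (1) joint-probability epoch rejection at `k_jp` SD
#' (single-channel and global); (2) per-epoch amplitude marking of channels
#' exceeding `amp_thresh` microvolts; (3) exclusion (interpolation across
#' all epochs) of channels marked in more than `bad_epoch_channel_frac` of
#' epochs; (4) rejection of epochs with more than
#' `max_bad_channels_per_epoch` marked channels; (5) spherical-spline
#' interpolation of the marked channels in the remaining epochs.
#'
#' @param epochs An [epoch_set()].
#' @param params A [cleaning_params()].
#' @param positions Electrode positions for interpolation.
#' @return List with `epochs` (cleaned) and `report`, a list recording the
#'   joint-probability mask, excluded channels, rejected epochs and every
#'   interpolation action.
#' @export
clean_epochs <- function(epochs, params = cleaning_params(),
                         positions = montage_positions(epochs$channels)) {
  stopifnot(inherits(epochs, "epoch_set"))
  report <- list()

  jp <- joint_probability_reject(epochs, k_single = params$k_jp,
                                 k_global = params$k_jp)
  report$jp_rejected <- which(jp$mask)
  epochs <- jp$epochs

  d <- dim(epochs$data)
  marked <- matrix(FALSE, nrow = d[1], ncol = d[3])
  for (e in seq_len(d[1]))
    marked[e, ] <- apply(abs(epochs$data[e, , , drop = FALSE]), 3, max) >
      params$amp_thresh

  frac <- colMeans(marked)
  excluded <- epochs$channels[frac > params$bad_epoch_channel_frac]
  report$excluded_channels <- excluded
  marked[, epochs$channels %in% excluded] <- TRUE

  n_bad <- rowSums(marked)
  drop_epoch <- n_bad > params$max_bad_channels_per_epoch
  report$amplitude_rejected <- which(drop_epoch)
  if (all(drop_epoch))
    stop("no epochs survive amplitude cleaning")
  epochs$data <- epochs$data[!drop_epoch, , , drop = FALSE]
  marked <- marked[!drop_epoch, , drop = FALSE]

  interp_log <- list()
  for (e in seq_len(dim(epochs$data)[1])) {
    bad <- epochs$channels[marked[e, ]]
    if (length(bad) == 0) next
    epochs$data[e, , ] <- spherical_interpolate(
      epochs$data[e, , ], epochs$channels, bad, positions)
    interp_log[[length(interp_log) + 1]] <-
      list(epoch = e, channels = bad)
  }
  report$interpolations <- interp_log
  report$n_epochs_out <- dim(epochs$data)[1]
  list(epochs = epochs, report = report)
}

#' Log-spaced wavelet frequency grid
#'
#' @param fmin,fmax Band edges in Hz (defaults 0.27 and 30).
#' @param n Number of steps (default 69).
#' @return Numeric vector `fmin * (fmax/fmin)^(k/(n-1))`, k = 0..n-1.
#' @export
tfr_freq_grid <- function(fmin = 0.27, fmax = 30, n = 69)
  fmin * (fmax / fmin)^((seq_len(n) - 1) / (n - 1))

#' Morlet continuous wavelet transform of an epoch set
#'
#' Analytic Morlet wavelet (Gaussian-windowed complex exponential) with a
#' fixed number of cycles, evaluated by FFT convolution at each grid
#' frequency. The wavelet is normalized to unit DC gain of its envelope, so
#' a unit-amplitude sinusoid at a grid frequency yields power 1/4 at that
#' frequency. Power is `|coefficient|^2`; averaging and the log10 transform
#' are applied downstream (see [mean_alpha_power()]).
#'
#' @param epochs An [epoch_set()].
#' @param freqs Frequency grid in Hz (default [tfr_freq_grid()]).
#' @param channels Channels to transform (default the five centro-parietal
#'   alpha channels Pz, POz, CPz, P3, P4).
#' @param n_cycles Wavelet width in cycles (default 3).
#' @return An object of class `tfr_grid`: list with `freqs`, `times`,
#'   `power` (array `[epoch, channel, freq, time]`), `channels`, `rate`.
#' @export
morlet_tfr <- function(epochs, freqs = tfr_freq_grid(),
                       channels = c("Pz", "POz", "CPz", "P3", "P4"),
                       n_cycles = 3) {
  stopifnot(inherits(epochs, "epoch_set"))
  channels <- intersect(channels, epochs$channels)
  if (length(channels) == 0) stop("no requested channel present")
  d <- dim(epochs$data)
  spe <- d[2]
  rate <- epochs$rate
  nfft <- 2^ceiling(log2(2 * spe))
  t_w <- (seq_len(nfft) - 1 - nfft / 2) / rate

  wav_fft <- matrix(0i, nrow = nfft, ncol = length(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma_t <- n_cycles / (2 * pi * f)
    w <- exp(-t_w^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t_w)
    w <- w / sum(exp(-t_w^2 / (2 * sigma_t^2)))
    wav_fft[, k] <- stats::fft(w)
  }
  # center the wavelet: convolution by FFT with the kernel shifted to t=0
  shift <- exp(2i * pi * (seq_len(nfft) - 1) * (nfft / 2) / nfft)

  power <- array(0, dim = c(d[1], length(channels), length(freqs), spe))
  ci <- match(channels, epochs$channels)
  for (e in seq_len(d[1])) {
    for (j in seq_along(channels)) {
      x_fft <- stats::fft(c(epochs$data[e, , ci[j]], numeric(nfft - spe)))
      for (k in seq_along(freqs)) {
        conv <- stats::fft(x_fft * wav_fft[, k] * shift,
                           inverse = TRUE) / nfft
        power[e, j, k, ] <- Mod(conv[seq_len(spe)])^2
      }
    }
  }
  structure(list(freqs = freqs, times = (seq_len(spe) - 1) / rate,
                 power = power, channels = channels, rate = rate),
            class = "tfr_grid")
}

#' Mean alpha power of a condition
#'
#' Averages wavelet power across epochs, applies log10 (with a floor of
#' 1e-12 to keep silent input finite), and means over the alpha band, the
#' analysis time window and the selected channels. The alternative order
#' (log10 per epoch, then average) is available via `log_each_epoch`.
#'
#' @param tfr A [morlet_tfr()] result.
#' @param band Frequency band in Hz (default `c(7, 13)`).
#' @param window Time window within the epoch in seconds (default
#'   `c(0.2, 1.8)`).
#' @param channels Channels to include (default: all channels in `tfr`).
#' @param log_each_epoch If `TRUE`, logarithmize per epoch before averaging.
#' @return List of class `alpha_summary_value`: `mean_alpha` (log10 power)
#'   and `n_epochs`.
#' @export
mean_alpha_power <- function(tfr, band = c(7, 13), window = c(0.2, 1.8),
                             channels = NULL, log_each_epoch = FALSE) {
  stopifnot(inherits(tfr, "tfr_grid"))
  if (is.null(channels)) channels <- tfr$channels
  ci <- match(channels, tfr$channels)
  if (anyNA(ci)) stop("channel not present in TFR")
  fi <- which(tfr$freqs >= band[1] - 1e-12 & tfr$freqs <= band[2] + 1e-12)
  ti <- which(tfr$times >= window[1] - 1e-12 &
                tfr$times <= window[2] + 1e-12)
  if (length(fi) == 0 || length(ti) == 0)
    stop("empty frequency band or time window")
  p <- tfr$power[, ci, fi, ti, drop = FALSE]
  floor_p <- 1e-12
  if (log_each_epoch) {
    val <- mean(log10(pmax(p, floor_p)))
  } else {
    avg <- apply(p, c(2, 3, 4), mean)  # average power across epochs first
    val <- mean(log10(pmax(avg, floor_p)))
  }
  list(mean_alpha = val, n_epochs = dim(tfr$power)[1])
}

#' Flag outlying alpha-power changes
#'
#' Per intervention, computes each subject's post-minus-pre change in mean
#' alpha power and flags subjects deviating more than `k` SDs from the mean
#' change.
#'
#' @param summaries data.frame with columns `subject`, `intervention`,
#'   `block` (`pre`/`post`) and `mean_alpha`.
#' @param k SD threshold (default 2).
#' @return data.frame with columns `subject`, `intervention`, `change`,
#'   `flagged`.
#' @export
flag_alpha_outliers <- function(summaries, k = 2) {
  stopifnot(all(c("subject", "intervention", "block", "mean_alpha") %in%
                  names(summaries)))
  out <- NULL
  for (iv in sort(unique(summaries$intervention))) {
    s <- summaries[summaries$intervention == iv, ]
    wide <- merge(s[s$block == "pre", c("subject", "mean_alpha")],
                  s[s$block == "post", c("subject", "mean_alpha")],
                  by = "subject", suffixes = c("_pre", "_post"))
    if (nrow(wide) < 3) stop("need at least 3 subjects per intervention")
    change <- wide$mean_alpha_post - wide$mean_alpha_pre
    sdv <- stats::sd(change)
    flag <- if (sdv == 0) rep(FALSE, length(change)) else
      abs(change - mean(change)) > k * sdv
    out <- rbind(out, data.frame(subject = wide$subject, intervention = iv,
                                 change = change, flagged = flag))
  }
  out[order(out$intervention, out$subject), ]
}
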