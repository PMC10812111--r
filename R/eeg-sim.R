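# Synthetic EEG: 1/f background + narrowband posterior alpha + blinks.
# Components are built in the frequency domain from seeded white spectra,
# which keeps the realization an exact function of (parameters, seed) and
# lets amplitude parameters scale components without changing the draws.

rand_spectrum_signal <- function(n, shape) {
  # real signal with amplitude spectrum `shape` (length floor(n/2)+1) and
  # random phases; unit-normalized later by the caller
  half <- length(shape)
  phases <- stats::runif(half, 0, 2 * pi)
  spec <- shape * exp(1i * phases)
  spec[1] <- 0
  full <- complex(real = numeric(n))
  full[1:half] <- spec
  if (n %% 2 == 0) {
    full[half] <- complex(real = Re(spec[half]))  # Nyquist bin real
    if (half > 2) full[n:(n - half + 3)] <- Conj(spec[2:(half - 1)])
  } else {
    full[n:(n - half + 2)] <- Conj(spec[2:half])
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

scale_rms <- function(x, rms) {
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s * rms
}

blink_template <- function(rate, duration = 0.35) {
  n <- round(duration * rate)
  sin(pi * seq_len(n) / n)^2
}

blink_weights <- function(channels) {
  w <- c(Fp1 = 1, Fp2 = 1, AFz = 0.6, F3 = 0.35, Fz = 0.3, F4 = 0.35,
         T7 = 0.05, C3 = 0.1, Cz = 0.08, C4 = 0.1, T8 = 0.05,
         CPz = 0.04, P7 = 0.02, P3 = 0.02, Pz = 0.02, P4 = 0.02, P8 = 0.02,
         POz = 0.01, O1 = 0.01, O2 = 0.01, M1 = 0.02, M2 = 0.02)
  out <- w[channels]
  out[is.na(out)] <- 0
  out
}

#' Generate a synthetic multichannel EEG recording
#'
#' Each channel is the sum of (i) 1/f^beta background noise, partially
#' shared across channels as in real recordings where volume conduction
#' spreads every cerebral source over the scalp (mixing weight
#' `noise_share`), (ii) a shared narrowband alpha oscillator at the
#' subject's IAF weighted by the posterior topography and scaled by the
#' design-cell amplitude multiplier, and (iii) blink transients on
#' frontal channels. Optionally a
#' large-amplitude sinusoidal stimulation artifact at the IAF is added
#' (used for the during-stimulation block). Units are microvolts.
#'
#' @param profile A [subject_profile()].
#' @param effect An [effect_spec()] or `NULL`.
#' @param session List with `intervention` ("active"/"sham") and `block`
#'   ("pre"/"during"/"post").
#' @param duration Recording length in seconds.
#' @param rate Sampling rate in Hz (default 500).
#' @param rng_seed Integer seed.
#' @param channels Channels to synthesize (default: full 22-channel montage).
#' @param stim_artifact_amp Amplitude (microvolts) of an added tACS artifact
#'   sinusoid at the IAF; 0 disables it.
#' @param stim_artifact_envelope Optional numeric envelope (one value per
#'   sample, recycled/truncated) shaping the artifact, e.g. a fade ramp.
#' @param noise_share Fraction (amplitude weight, 0-1) of the 1/f
#'   background shared across all channels; the rest is channel-specific.
#' @return An [eeg_recording()].
#' @export
generate_eeg <- function(profile, effect = NULL,
                         session = list(intervention = "sham", block = "pre"),
                         duration = 120, rate = 500, rng_seed = 1,
                         channels = montage_channels(),
                         stim_artifact_amp = 0,
                         stim_artifact_envelope = NULL,
                         noise_share = 0.75) {
  stopifnot(inherits(profile, "subject_profile"), duration > 0)
  unknown <- setdiff(channels, names(profile$alpha_gain))
  if (length(unknown) > 0)
    stop("no alpha gain for channel(s): ", paste(unknown, collapse = ", "))
  set.seed(rng_seed)
  n <- round(duration * rate)
  half <- floor(n / 2) + 1
  freqs <- (seq_len(half) - 1) * rate / n
  mult <- alpha_multiplier(effect, session$intervention, session$block)

  # shared alpha source: Gaussian spectral bump at the IAF
  sigma_f <- profile$alpha_bw / (2 * sqrt(2 * log(2)))
  alpha_shape <- exp(-(freqs - profile$iaf)^2 / (2 * sigma_f^2))
  alpha_src <- scale_rms(rand_spectrum_signal(n, alpha_shape),
                         1 / sqrt(2))  # RMS of a unit-amplitude sinusoid

  beta <- profile$one_over_f_exponent
  noise_shape <- 1 / (pmax(freqs, 0.1))^(beta / 2)
  noise_shape[freqs > 0.45 * rate] <- 0

  tmpl <- blink_template(rate)
  bw <- blink_weights(channels)
  n_blinks <- stats::rpois(1, profile$blink_rate * duration / 60)
  blink_onsets <- sort(stats::runif(n_blinks, 0, duration - 0.4))
  blink_amps <- 120 * (0.8 + 0.4 * stats::runif(n_blinks))
  blink_sig <- numeric(n)
  for (k in seq_len(n_blinks)) {
    i0 <- round(blink_onsets[k] * rate) + 1
    idx <- i0:(i0 + length(tmpl) - 1)
    idx <- idx[idx <= n]
    blink_sig[idx] <- blink_sig[idx] + blink_amps[k] * tmpl[seq_along(idx)]
  }

  shared_noise <- scale_rms(rand_spectrum_signal(n, noise_shape), 1)
  w_own <- sqrt(1 - noise_share^2)
  data <- matrix(0, nrow = n, ncol = length(channels))
  for (j in seq_along(channels)) {
    ch <- channels[j]
    own <- scale_rms(rand_spectrum_signal(n, noise_shape), 1)
    noise <- profile$noise_rms * (noise_share * shared_noise + w_own * own)
    data[, j] <- noise +
      profile$alpha_amp * mult * profile$alpha_gain[[ch]] * alpha_src +
      bw[[j]] * blink_sig
  }

  if (stim_artifact_amp > 0) {
    t <- (seq_len(n) - 1) / rate
    env <- if (is.null(stim_artifact_envelope)) rep(1, n) else {
      e <- stim_artifact_envelope
      if (length(e) >= n) e[seq_len(n)] else c(e, rep(0, n - length(e)))
    }
    art <- stim_artifact_amp * env * sin(2 * pi * profile$iaf * t)
    data <- data + outer(art, rep(1, length(channels)))
  }

  eeg_recording(data, rate, channels,
                meta = list(session = session, iaf = profile$iaf,
                            alpha_multiplier = mult))
}

#' Generate a tACS current waveform
#'
#' Active stimulation is a sinusoid at the individual alpha frequency with
#' linear fade-in/fade-out ramps; sham stimulation is a 30 s waveform made
#' of a 10 s fade-in, 10 s plateau and 10 s fade-out, mimicking the skin
#' sensation of stimulation onset without sustained entrainment.
#'
#' @param mode `"active"` or `"sham"`.
#' @param iaf Stimulation frequency in Hz.
#' @param amplitude Peak current in mA (default 1.5).
#' @param fade Ramp length in seconds (default 10).
#' @param active_duration Total active-stimulation length in seconds
#'   (default 1080 = 18 min).
#' @param rate Waveform sampling rate in Hz.
#' @return An object of class `stim_waveform`: list with `t` (s), `current`
#'   (mA), `mode`, `frequency`, `amplitude`, `fade` and the `envelope`.
#' @export
generate_stim_waveform <- function(mode = c("active", "sham"), iaf = 10,
                                   amplitude = 1.5, fade = 10,
                                   active_duration = 1080, rate = 500) {
  mode <- match.arg(mode)
  total <- if (mode == "active") active_duration else 3 * fade
  n <- round(total * rate)
  t <- (seq_len(n) - 1) / rate
  if (mode == "active") {
    env <- pmin(1, pmin(t / fade, (total - t) / fade))
  } else {
    env <- pmin(1, pmin(t / fade, (total - t) / fade))
    # sham: fade-in, plateau of one fade-length, fade-out (3 * fade total)
  }
  env <- pmax(env, 0)
  structure(list(t = t, current = amplitude * env * sin(2 * pi * iaf * t),
                 envelope = env, mode = mode, frequency = iaf,
                 amplitude = amplitude, fade = fade),
            class = "stim_waveform")
}

#' @export
print.stim_waveform <- function(x, ...) {
  cat(sprintf("<stim_waveform> %s, %.2f Hz, %.2f mA, %.0f s\n",
              x$mode, x$frequency, x$amplitude,
              length(x$t) * diff(x$t[1:2])))
  invisible(x)
}
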