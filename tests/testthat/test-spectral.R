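test_that("epoching splits the recording and drops the remainder", {
  rec <- generate_eeg(subject_profile(), duration = 121, rng_seed = 2,
                      channels = c("Pz", "Cz"))
  ep <- filter_and_epoch(rec)
  expect_equal(n_epochs(ep), 60)
  expect_error(filter_and_epoch(
    eeg_recording(matrix(rnorm(100), ncol = 1), 500, "Pz")), "epoch")
})

test_that("the band-pass stops DC and preserves a 10 Hz tone", {
  n <- 500 * 10
  dc <- eeg_recording(matrix(rep(7, n), ncol = 1), 500, "Pz")
  ep <- filter_and_epoch(dc)
  expect_lt(max(abs(ep$data)), 0.5)
  t <- (1:n) / 500
  tone <- eeg_recording(matrix(sin(2 * pi * 10 * t), ncol = 1), 500, "Pz")
  ep <- filter_and_epoch(tone)
  mid <- ep$data[3, 100:900, 1]  # away from filter edges
  expect_lt(abs(max(mid) - 1), 0.05)
})

test_that("an amplified epoch among Gaussian epochs is rejected at k=2", {
  set.seed(8)
  arr <- array(rnorm(50 * 500 * 2), dim = c(50, 500, 2))
  arr[17, , ] <- 20 * arr[17, , ]
  ep <- epoch_set(arr, 250, c("Pz", "Cz"))
  res <- joint_probability_reject(ep, 2, 2)
  expect_true(res$mask[17])
})

test_that("identical epochs produce zero-variance statistics and no rejection", {
  arr <- array(rep(sin(2 * pi * 10 * (1:500) / 250), each = 5),
               dim = c(5, 500, 1))
  for (e in 1:5) arr[e, , 1] <- sin(2 * pi * 10 * (1:500) / 250)
  ep <- epoch_set(arr, 250, "Pz")
  res <- joint_probability_reject(ep, 2, 2)
  expect_false(any(res$mask))
})

test_that("a tighter threshold rejects a superset of epochs", {
  ep <- correlated_gaussian_epochs(n_ep = 40, seed = 3)
  loose <- joint_probability_reject(ep, 2.0, 2.0)$mask
  tight <- joint_probability_reject(ep, 1.7, 1.7)$mask
  expect_true(all(which(loose) %in% which(tight)))
})

test_that("the rejection mask is invariant to channel ordering", {
  ep <- correlated_gaussian_epochs(n_ep = 30, seed = 5)
  perm <- sample(seq_along(ep$channels))
  ep_perm <- epoch_set(ep$data[, , perm, drop = FALSE], ep$rate,
                       ep$channels[perm])
  expect_identical(joint_probability_reject(ep, 2, 2)$mask,
                   joint_probability_reject(ep_perm, 2, 2)$mask)
})

test_that("the spectrum grid has the configured 0.05 Hz spacing", {
  ep <- tone_epochs(10, rate = 500)
  ps <- log_power_spectrum(ep, "Pz")
  expect_equal(unique(round(diff(ps$freqs), 10)), 0.05)
  expect_lte(max(ps$freqs), 40)
  expect_error(log_power_spectrum(ep, "Pz", resolution = 0.7), "coarser")
})

test_that("a pure tone peaks at its own frequency bin", {
  ep <- tone_epochs(10, rate = 500)
  ps <- log_power_spectrum(ep, "Pz")
  expect_equal(ps$freqs[which.max(ps$log_power)], 10)
})

test_that("doubling the amplitude raises peak log power by log10(4)", {
  p1 <- log_power_spectrum(tone_epochs(10, 1, rate = 500), "Pz")
  p2 <- log_power_spectrum(tone_epochs(10, 2, rate = 500), "Pz")
  expect_equal(max(p2$log_power) - max(p1$log_power), log10(4),
               tolerance = 0.01 / log10(4))
})

test_that("IAF detection picks the maximum, breaks ties low, flags flat bands", {
  freqs <- seq(0, 40, by = 0.05)
  lp <- rep(-3, length(freqs))
  lp[freqs == 8] <- -1; lp[freqs == 11] <- -0.5
  spec <- structure(list(freqs = freqs, log_power = lp,
                         n_epochs_averaged = 1), class = "power_spectrum")
  expect_equal(detect_iaf(spec)$iaf, 11)
  flat <- structure(list(freqs = freqs, log_power = rep(-3, length(freqs)),
                         n_epochs_averaged = 1), class = "power_spectrum")
  expect_warning(res <- detect_iaf(flat), "flat")
  expect_equal(res$iaf, 7)
  expect_error(detect_iaf(spec, band = c(50, 60)), "empty")
})

test_that("a synthetic 9.5 Hz alpha subject is recovered within one bin", {
  p <- subject_profile(iaf = 9.5, alpha_amp = 25)
  rec <- generate_eeg(p, duration = 120, rng_seed = 14)
  expect_lt(abs(iaf_from_rest(rec)$iaf - 9.5), 0.05 + 1e-9)
})

test_that("blink regression removes frontal transients but keeps alpha", {
  p <- subject_profile(blink_rate = 20, alpha_amp = 15)
  rec <- generate_eeg(p, duration = 30, rng_seed = 19)
  clean <- remove_blink_artifacts(rec)
  # strong reduction of slow frontal power at Fp1
  slow_power <- function(r, ch) {
    x <- r$data[, ch]
    n <- length(x)
    f <- (0:(floor(n / 2))) * r$rate / n
    pxx <- Mod(stats::fft(x)[1:(floor(n / 2) + 1)])^2
    c(slow = mean(pxx[f >= 0.5 & f <= 4]),
      alpha = mean(pxx[f >= 8 & f <= 11]))
  }
  before <- slow_power(rec, "Fp1"); after <- slow_power(clean, "Fp1")
  expect_lt(after[["slow"]], 0.35 * before[["slow"]])
  pz_b <- slow_power(rec, "Pz"); pz_a <- slow_power(clean, "Pz")
  expect_gt(pz_a[["alpha"]], 0.9 * pz_b[["alpha"]])
})
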