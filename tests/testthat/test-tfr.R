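test_that("preprocessing yields the 250 Hz grid, attenuates 60 Hz, detrends ramps", {
  t <- (0:4999) / 500
  tone <- eeg_recording(matrix(50 * sin(2 * pi * 60 * t), ncol = 1),
                        500, "Pz")
  out <- preprocess_continuous(tone)
  expect_equal(out$rate, 250)                 # 0.004 s sampling interval
  mid <- out$data[500:2000, 1]                # steady-state region
  rms_in <- 50 / sqrt(2)
  expect_lt(sqrt(mean(mid^2)) / rms_in, 0.01) # < 1% residual amplitude

  ramp <- eeg_recording(matrix(seq(0, 100, length.out = 5000), ncol = 1),
                        500, "Pz")
  dt <- preprocess_continuous(ramp)
  expect_lt(abs(mean(dt$data)), 1e-6)
  tc <- seq_len(nrow(dt$data)) - mean(seq_len(nrow(dt$data)))
  expect_lt(abs(sum(dt$data[, 1] * tc) / sum(tc^2)), 1e-8)
})

test_that("channel exclusion and epoch rejection follow the printed rules", {
  set.seed(6)
  n_ep <- 20; rate <- 250; spe <- 500
  ch <- montage_channels()
  # correlated background keeps the improbability stage quiet
  base <- correlated_gaussian_epochs(n_ep = n_ep, rate = rate, seed = 10)
  arr <- base$data
  # channel P7 exceeds 150 uV in 4 of 20 epochs (20% > 15% -> excluded)
  j <- which(ch == "P7")
  for (e in c(2, 5, 11, 17)) arr[e, 100:120, j] <- 400
  # epoch 9 has 11 channels above threshold (> 10 -> rejected)
  arr[9, 200:220, 1:11] <- 400
  ep <- epoch_set(arr, rate, ch)
  res <- clean_epochs(ep, cleaning_params())
  expect_true("P7" %in% res$report$excluded_channels)
  expect_true(all(abs(res$epochs$data) < 400))
  # epoch 9 (after the jp stage's renumbering) must be gone: nothing in
  # the output retains its 11-channel artifact signature
  expect_true(res$report$n_epochs_out < n_ep)
  expect_error(clean_epochs(ep, cleaning_params(amp_thresh = 1e-9)),
               "survive")
})

test_that("clean correlated data survives cleaning mostly intact", {
  ep <- correlated_gaussian_epochs(n_ep = 40, seed = 12)
  res <- clean_epochs(ep, cleaning_params())
  expect_equal(res$report$excluded_channels, character(0))
  expect_equal(length(res$report$amplitude_rejected), 0)
  expect_gte(res$report$n_epochs_out / 40, 0.75)
  # a second pass performs no amplitude-driven actions
  res2 <- clean_epochs(res$epochs, cleaning_params())
  expect_equal(res2$report$excluded_channels, character(0))
  expect_equal(length(res2$report$amplitude_rejected), 0)
  expect_equal(length(res2$report$interpolations), 0)
})

test_that("the wavelet grid is the 69-step log scale from 0.27 to 30 Hz", {
  g <- tfr_freq_grid()
  expect_equal(length(g), 69)
  expect_equal(g[1], 0.27)
  expect_equal(g[69], 30)
  expect_equal(unique(round(diff(log(g)), 12)),
               round(log(30 / 0.27) / 68, 12))
})

test_that("Morlet power on pure tones matches the Gaussian closed form", {
  grid <- tfr_freq_grid()
  for (f0 in c(grid[which.min(abs(grid - 5))],
               grid[which.min(abs(grid - 10))],
               grid[which.min(abs(grid - 20))])) {
    tfr <- morlet_tfr(tone_epochs(f0, n_ep = 1), channels = "Pz")
    ti <- tfr$times >= 0.5 & tfr$times <= 1.5
    k0 <- which.min(abs(grid - f0))
    for (k in (k0 - 2):(k0 + 2)) {
      sigma_t <- 3 / (2 * pi * grid[k])
      pred <- 0.25 * exp(-4 * pi^2 * sigma_t^2 * (grid[k] - f0)^2)
      got <- mean(tfr$power[1, 1, k, ti])
      expect_lt(abs(got - pred) / pred, 0.02)
    }
  }
})

test_that("the wavelet is frequency selective around 10 Hz", {
  grid <- tfr_freq_grid()
  f0 <- grid[which.min(abs(grid - 10))]
  tfr <- morlet_tfr(tone_epochs(f0, n_ep = 1), channels = "Pz")
  ti <- tfr$times >= 0.5 & tfr$times <= 1.5
  p10 <- mean(tfr$power[1, 1, which.min(abs(grid - 10)), ti])
  p20 <- mean(tfr$power[1, 1, which.min(abs(grid - 20)), ti])
  expect_gt(p10 / p20, 8)
})

test_that("silent epochs give floored finite log power", {
  ep <- tone_epochs(10, amplitude = 0, n_ep = 2)
  tfr <- morlet_tfr(ep, channels = "Pz")
  expect_true(all(tfr$power == 0))
  mp <- mean_alpha_power(tfr)
  expect_equal(mp$mean_alpha, -12)
})

test_that("alpha summaries scale with amplitude and ignore epoch order", {
  ep1 <- tone_epochs(10, 1, n_ep = 4)
  ep2 <- tone_epochs(10, 2, n_ep = 4)
  m1 <- mean_alpha_power(morlet_tfr(ep1, channels = "Pz"))
  m2 <- mean_alpha_power(morlet_tfr(ep2, channels = "Pz"))
  expect_equal(m2$mean_alpha - m1$mean_alpha, log10(4),
               tolerance = 0.01 / log10(4))

  set.seed(9)
  arr <- array(rnorm(6 * 500 * 1), dim = c(6, 500, 1))
  ep <- epoch_set(arr, 250, "Pz")
  perm <- epoch_set(arr[c(4, 1, 6, 2, 5, 3), , , drop = FALSE], 250, "Pz")
  expect_identical(mean_alpha_power(morlet_tfr(ep, channels = "Pz")),
                   mean_alpha_power(morlet_tfr(perm, channels = "Pz")))
})

test_that("both logarithm orders are available and differ on variable data", {
  set.seed(10)
  arr <- array(rnorm(6 * 500), dim = c(6, 500, 1))
  arr[1, , ] <- arr[1, , ] * 5
  tfr <- morlet_tfr(epoch_set(arr, 250, "Pz"), channels = "Pz")
  after <- mean_alpha_power(tfr)$mean_alpha
  each <- mean_alpha_power(tfr, log_each_epoch = TRUE)$mean_alpha
  expect_gt(after, each)  # Jensen: log of mean >= mean of logs
})

test_that("an injected pre-to-post multiplier is recovered as 2 log10(m)", {
  eff <- effect_spec(pre_post_multiplier_sham = 1.5,
                     pre_post_multiplier_active = 1.5,
                     log_alpha_subject_sd = 0)
  d <- sapply(1:6, function(i) {
    p <- subject_profile(alpha_amp = 25, blink_rate = 0)
    val <- function(block, seed) {
      rec <- generate_eeg(p, eff, list(intervention = "sham",
                                       block = block),
                          duration = 16, rate = 500, rng_seed = seed,
                          channels = c("Pz", "POz", "CPz", "P3", "P4"))
      rec <- preprocess_continuous(rec)
      mean_alpha_power(morlet_tfr(epoch_recording(rec)))$mean_alpha
    }
    val("post", 300 + i) - val("pre", 600 + i)
  })
  expect_lt(abs(mean(d) - 2 * log10(1.5)), 0.1)
})

test_that("outlier flags mark extreme changes and ignore subject order", {
  s <- sprintf("s%02d", 1:15)
  df <- rbind(
    data.frame(subject = s, intervention = "active", block = "pre",
               mean_alpha = 3),
    data.frame(subject = s, intervention = "active", block = "post",
               mean_alpha = 3.5 + c(rep(0, 14), 5) +
                 seq(-0.07, 0.07, length.out = 15)))
  flags <- flag_alpha_outliers(df)
  expect_true(flags$flagged[flags$subject == "s15"])
  expect_equal(sum(flags$flagged), 1)
  perm <- df[sample(nrow(df)), ]
  expect_equal(flag_alpha_outliers(perm), flags)

  same <- df
  same$mean_alpha[same$block == "post"] <- 4
  expect_false(any(flag_alpha_outliers(same)$flagged))
})
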