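# Shared micro-scale fixtures: full design structure at a fraction of the
# run time. All data are generated in code at test time.

micro_cpt_spec <- function() {
  cpt_block_spec(
    n_pairs = 25, n_targets = 8, n_pseudo = 9, phase_length = 10,
    n_distractors = 6,
    distractor_modality_counts = c(visual = 2, auditory = 2,
                                   audiovisual = 2),
    distractor_duration = 2)
}

micro_cohort_config <- function(out_dir, n_subjects = 2) {
  cohort_config(n_subjects = n_subjects, out_dir = out_dir,
                cpt_spec = micro_cpt_spec(),
                block_duration = 20, rest_duration = 20)
}

# epochs of correlated Gaussian noise shaped like resting EEG (shared
# sources spread over all channels by volume conduction)
correlated_gaussian_epochs <- function(n_ep = 40, rate = 250,
                                       channels = montage_channels(),
                                       seed = 1) {
  set.seed(seed)
  spe <- 2 * rate
  n_ch <- length(channels)
  n_src <- 4
  mix <- matrix(stats::runif(n_src * n_ch, 0.3, 1), n_src, n_ch)
  arr <- array(0, dim = c(n_ep, spe, n_ch))
  for (e in seq_len(n_ep)) {
    src <- matrix(stats::rnorm(spe * n_src, sd = 10), spe, n_src)
    arr[e, , ] <- src %*% mix +
      matrix(stats::rnorm(spe * n_ch, sd = 3), spe, n_ch)
  }
  epoch_set(arr, rate, channels)
}

# single-tone epoch set at a given frequency and amplitude
tone_epochs <- function(freq, amplitude = 1, n_ep = 3, rate = 250,
                        channels = "Pz") {
  spe <- 2 * rate
  t <- (seq_len(spe) - 1) / rate
  arr <- array(0, dim = c(n_ep, spe, length(channels)))
  for (e in seq_len(n_ep)) for (ch in seq_along(channels))
    arr[e, , ch] <- amplitude * cos(2 * pi * freq * t)
  epoch_set(arr, rate, channels)
}

# brute-force within-subject sums of squares by explicit enumeration;
# independent of the package's mean-based computation
brute_force_anova <- function(table) {
  subs <- unique(table$subject)
  n <- length(subs)
  y <- function(s, iv, bl)
    table$value[table$subject == s & table$intervention == iv &
                  table$block == bl]
  grand <- mean(table$value)
  ss <- list(block = 0, iv = 0, int = 0, bs = 0, is = 0, bis = 0)
  bl_mean <- sapply(c("pre", "post"), function(b)
    mean(table$value[table$block == b]))
  iv_mean <- sapply(c("active", "sham"), function(i)
    mean(table$value[table$intervention == i]))
  cell_mean <- function(iv, bl) mean(table$value[
    table$intervention == iv & table$block == bl])
  s_mean <- sapply(subs, function(s) mean(table$value[table$subject == s]))
  names(s_mean) <- subs
  sb_mean <- function(s, bl) mean(table$value[table$subject == s &
                                                table$block == bl])
  si_mean <- function(s, iv) mean(table$value[table$subject == s &
                                                table$intervention == iv])
  for (bl in c("pre", "post"))
    ss$block <- ss$block + 2 * n * (bl_mean[bl] - grand)^2
  for (iv in c("active", "sham"))
    ss$iv <- ss$iv + 2 * n * (iv_mean[iv] - grand)^2
  for (iv in c("active", "sham")) for (bl in c("pre", "post"))
    ss$int <- ss$int + n * (cell_mean(iv, bl) - iv_mean[iv] -
                              bl_mean[bl] + grand)^2
  for (s in subs) for (bl in c("pre", "post"))
    ss$bs <- ss$bs + 2 * (sb_mean(s, bl) - s_mean[s] - bl_mean[bl] +
                            grand)^2
  for (s in subs) for (iv in c("active", "sham"))
    ss$is <- ss$is + 2 * (si_mean(s, iv) - s_mean[s] - iv_mean[iv] +
                            grand)^2
  for (s in subs) for (iv in c("active", "sham")) for (bl in c("pre",
                                                               "post"))
    ss$bis <- ss$bis + (y(s, iv, bl) - sb_mean(s, bl) - si_mean(s, iv) -
                          cell_mean(iv, bl) + s_mean[s] + bl_mean[bl] +
                          iv_mean[iv] - grand)^2
  df2 <- n - 1
  data.frame(
    effect = c("Block", "Intervention", "Interaction"),
    F = c(ss$block / (ss$bs / df2), ss$iv / (ss$is / df2),
          ss$int / (ss$bis / df2)),
    partial_eta_sq = c(ss$block / (ss$block + ss$bs),
                       ss$iv / (ss$iv + ss$is),
                       ss$int / (ss$int + ss$bis)),
    stringsAsFactors = FALSE)
}
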