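# On-disk synthetic cohorts: a BIDS-style tree with EDF EEG per block and
# resting phase, plus tab-separated event, response, gaze, head-tracking
# and rating streams. Everything is a pure function of (config, seed).

#' Configuration of a synthetic crossover cohort
#'
#' Defaults describe the scaled-down study: the full 450-pair CPT schedule
#' (counts are never scaled), 3-min EEG per block and 2-min resting phases.
#' `full_scale = TRUE` restores 18-min EEG blocks.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param out_dir Root directory for the generated tree.
#' @param cpt_spec A [cpt_block_spec()]; also sets gaze/head-track length.
#' @param effect An [effect_spec()].
#' @param block_duration EEG seconds recorded per CPT block (default 180).
#' @param rest_duration Resting EEG seconds (default 120).
#' @param rate,gaze_rate,track_rate Sampling rates in Hz.
#' @param iaf_mean,iaf_sd Population mean and SD of the individual alpha
#'   frequency (defaults 9.65 and 0.8 Hz).
#' @param alpha_amp_mean,alpha_amp_sd Population alpha amplitude (uV).
#' @param stim_artifact_amp Amplitude of the during-block tACS artifact
#'   (uV).
#' @param full_scale If `TRUE`, EEG blocks span the full CPT duration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 15, out_dir = tempfile("cohort"),
                          cpt_spec = cpt_block_spec(),
                          effect = effect_spec(),
                          block_duration = 180, rest_duration = 120,
                          rate = 500, gaze_rate = 50, track_rate = 90,
                          iaf_mean = 9.65, iaf_sd = 0.8,
                          alpha_amp_mean = 10, alpha_amp_sd = 2,
                          stim_artifact_amp = 2000,
                          full_scale = FALSE) {
  stopifnot(n_subjects >= 1, block_duration > 0, rest_duration > 0)
  if (full_scale) block_duration <- cpt_block_duration(cpt_spec)
  structure(list(n_subjects = n_subjects, out_dir = out_dir,
                 cpt_spec = cpt_spec, effect = effect,
                 block_duration = block_duration,
                 rest_duration = rest_duration, rate = rate,
                 gaze_rate = gaze_rate, track_rate = track_rate,
                 iaf_mean = iaf_mean, iaf_sd = iaf_sd,
                 alpha_amp_mean = alpha_amp_mean,
                 alpha_amp_sd = alpha_amp_sd,
                 stim_artifact_amp = stim_artifact_amp,
                 full_scale = full_scale),
            class = "cohort_config")
}

derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (seed %% 100000) * 10007
  for (i in seq_along(idx)) s <- s + idx[i] * 97L^i
  as.integer(s %% 2147483647)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
}

read_tsv <- function(path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "n/a")

draw_profile <- function(config, seed) {
  set.seed(seed)
  iaf <- min(13, max(7, stats::rnorm(1, config$iaf_mean, config$iaf_sd)))
  amp <- max(2, stats::rnorm(1, config$alpha_amp_mean, config$alpha_amp_sd))
  subject_profile(
    iaf = iaf, alpha_amp = amp,
    p_hit = min(0.98, max(0.5, stats::rnorm(1, 0.85, 0.07))),
    p_fa_pseudo = min(0.3, max(0.01, stats::rnorm(1, 0.06, 0.02))),
    rt_mu = stats::rnorm(1, log(450), 0.1),
    rt_sigma = max(0.1, stats::rnorm(1, 0.25, 0.05)),
    restlessness = max(1, stats::rnorm(1, 6, 1.5)),
    rot_restlessness = max(0.5, stats::rnorm(1, 3, 0.8))
  )
}

events_frame <- function(schedule, block) {
  tr <- schedule$trials
  phase_of <- function(t) {
    i <- findInterval(t, schedule$phases$start)
    schedule$phases$kind[pmax(i, 1)]
  }
  letters <- data.frame(
    block = block,
    onset = c(tr$onset1, tr$onset2),
    duration = schedule$spec$letter_duration,
    trial_type = "letter",
    pair_index = c(tr$pair_index, tr$pair_index),
    slot = rep(c(1L, 2L), each = nrow(tr)),
    letter = c(tr$letter1, tr$letter2),
    is_target = c(tr$is_target, tr$is_target),
    is_pseudo = c(tr$is_pseudo, tr$is_pseudo),
    phase = phase_of(c(tr$onset1, tr$onset2)),
    modality = NA_character_, stringsAsFactors = FALSE)
  ev <- schedule$distractors
  if (nrow(ev) > 0) {
    distr <- data.frame(
      block = block, onset = ev$onset, duration = ev$duration,
      trial_type = "distractor", pair_index = NA_integer_,
      slot = NA_integer_, letter = NA_character_, is_target = NA,
      is_pseudo = NA, phase = "DP", modality = ev$modality,
      stringsAsFactors = FALSE)
    letters <- rbind(letters, distr)
  }
  letters[order(letters$onset), ]
}

#' Rebuild a CPT schedule from an events table
#'
#' Inverse of the events serialization in [generate_cohort()]: pairs the
#' two letter rows of each pair index back into a trials table so the
#' scoring functions can run from disk.
#'
#' @param events data.frame in the events.tsv layout.
#' @param block Block number to extract.
#' @return A `cpt_schedule`-classed list (trials, distractors; no spec).
#' @export
events_to_schedule <- function(events, block) {
  ev <- events[events$block == block, ]
  lt <- ev[ev$trial_type == "letter", ]
  s1 <- lt[lt$slot == 1, ]
  s2 <- lt[lt$slot == 2, ]
  s1 <- s1[order(s1$pair_index), ]
  s2 <- s2[order(s2$pair_index), ]
  trials <- data.frame(
    pair_index = s1$pair_index, letter1 = s1$letter, letter2 = s2$letter,
    onset1 = s1$onset, onset2 = s2$onset,
    is_target = as.logical(s1$is_target),
    is_pseudo = as.logical(s1$is_pseudo), stringsAsFactors = FALSE)
  d <- ev[ev$trial_type == "distractor", ]
  distractors <- data.frame(event_id = seq_len(nrow(d)),
                            modality = d$modality, onset = d$onset,
                            duration = d$duration, stringsAsFactors = FALSE)
  structure(list(trials = trials, phases = NULL, distractors = distractors,
                 spec = NULL), class = "cpt_schedule")
}

block_label <- function(block) c("pre", "during", "post")[block]

generate_session <- function(config, subject, intervention, ses_dir, seed) {
  dir.create(ses_dir, recursive = TRUE, showWarnings = FALSE)
  profile <- draw_profile(config, derive_seed(seed, subject, 1))
  prefix <- file.path(ses_dir, sprintf("sub-%02d_ses-%s", subject,
                                       intervention))
  iv_idx <- if (intervention == "active") 1L else 2L
  events <- NULL; responses <- NULL; gaze <- NULL; track <- NULL
  ratings <- NULL

  # subject- and intervention-specific alpha multiplier noise
  set.seed(derive_seed(seed, subject, iv_idx, 90))
  mult_noise <- 10^stats::rnorm(2, 0, config$effect$log_alpha_subject_sd)

  for (block in 1:3) {
    bl <- block_label(block)
    session <- list(intervention = intervention, block = bl)
    schedule <- generate_cpt_block(
      config$cpt_spec, derive_seed(seed, subject, iv_idx, block, 1))

    eff <- config$effect
    art_amp <- 0; art_env <- NULL
    if (bl == "during" && config$stim_artifact_amp > 0) {
      wf <- generate_stim_waveform(
        if (intervention == "active") "active" else "sham",
        iaf = profile$iaf, rate = config$rate,
        active_duration = config$block_duration)
      art_amp <- config$stim_artifact_amp
      art_env <- wf$envelope
    }
    prof_b <- profile
    if (bl == "post") {
      mult <- alpha_multiplier(eff, intervention, "post") *
        mult_noise[if (intervention == "active") 1 else 2]
      prof_b$alpha_amp <- profile$alpha_amp * mult
    }
    rec <- generate_eeg(prof_b, effect = NULL,
                        session = session,
                        duration = config$block_duration,
                        rate = config$rate,
                        rng_seed = derive_seed(seed, subject, iv_idx,
                                               block, 2),
                        stim_artifact_amp = art_amp,
                        stim_artifact_envelope = art_env)
    write_edf(rec, sprintf("%s_task-cpt_block-%d_eeg.edf", prefix, block),
              patient = sprintf("sub-%02d", subject))

    be <- list(
      p_hit_mult = if (bl == "post") 1 / eff$omission_post_mult else 1,
      p_fa_mult = if (bl == "post") eff$commission_post_mult else 1)
    resp <- generate_responses(schedule, profile, block_effects = be,
                               rng_seed = derive_seed(seed, subject,
                                                      iv_idx, block, 3))
    events <- rbind(events, events_frame(schedule, block))
    if (nrow(resp) > 0)
      responses <- rbind(responses,
                         data.frame(block = block, time = resp$time))

    g <- generate_gaze(schedule, profile,
                       rng_seed = derive_seed(seed, subject, iv_idx,
                                              block, 4),
                       rate = config$gaze_rate,
                       p_distract_mult = if (bl == "post")
                         eff$distractor_gaze_post_mult else 1)
    gaze <- rbind(gaze, cbind(block = block, as.data.frame(g)))

    h <- generate_head_track(profile, effect = eff, session = session,
                             duration = cpt_block_duration(config$cpt_spec),
                             rate = config$track_rate,
                             rng_seed = derive_seed(seed, subject, iv_idx,
                                                    block, 5))
    track <- rbind(track, cbind(block = block, as.data.frame(h)))

    set.seed(derive_seed(seed, subject, iv_idx, block, 6))
    shift <- config$effect$rating_post_shift
    base <- c(inattention = 1, hyperactivity = 1.19, impulsivity = 0.5)
    for (scale in names(base)) {
      mu <- base[[scale]] + if (bl == "post") shift[[scale]] else 0
      val <- round(mu + stats::rnorm(1, 0, 0.8))
      ratings <- rbind(ratings, data.frame(
        block = block, scale = scale,
        value = max(-3, min(3, val)), stringsAsFactors = FALSE))
    }
  }

  # resting EEG: baseline (pre-experiment, IAF), pre (after block 1),
  # post (after block 3)
  rest_specs <- list(baseline = "pre", pre = "pre", post = "post")
  k <- 0
  for (nm in names(rest_specs)) {
    k <- k + 1
    bl <- rest_specs[[nm]]
    prof_b <- profile
    if (bl == "post") {
      mult <- alpha_multiplier(config$effect, intervention, "post") *
        mult_noise[if (intervention == "active") 1 else 2]
      prof_b$alpha_amp <- profile$alpha_amp * mult
    }
    rec <- generate_eeg(prof_b, session = list(intervention = intervention,
                                               block = bl),
                        duration = config$rest_duration,
                        rate = config$rate,
                        rng_seed = derive_seed(seed, subject, iv_idx,
                                               10 + k, 2))
    write_edf(rec, sprintf("%s_rest-%s_eeg.edf", prefix, nm),
              patient = sprintf("sub-%02d", subject))
  }

  write_tsv(events, sprintf("%s_events.tsv", prefix))
  write_tsv(responses, sprintf("%s_responses.tsv", prefix))
  write_tsv(gaze, sprintf("%s_gaze.tsv", prefix))
  write_tsv(track, sprintf("%s_headtrack.tsv", prefix))
  write_tsv(ratings, sprintf("%s_ratings.tsv", prefix))
  invisible(profile)
}

#' Generate a complete synthetic crossover cohort on disk
#'
#' Writes `sub-XX/ses-{active,sham}/` session directories containing EDF
#' EEG for the three CPT blocks and three resting phases, plus events,
#' responses, gaze, head-tracking and rating TSVs, fully reproducible from
#' `(config, seed)`. The order of interventions alternates across subjects
#' (counterbalancing) and is recorded in `participants.tsv`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return The cohort root directory, invisibly.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  root <- config$out_dir
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  participants <- NULL
  for (s in seq_len(config$n_subjects)) {
    first <- if (s %% 2 == 1) "active" else "sham"
    order <- if (first == "active") c("active", "sham") else
      c("sham", "active")
    for (iv in order) {
      ses_dir <- file.path(root, sprintf("sub-%02d", s),
                           sprintf("ses-%s", iv))
      generate_session(config, s, iv, ses_dir, seed)
    }
    participants <- rbind(participants, data.frame(
      subject = sprintf("sub-%02d", s), first_intervention = first,
      stringsAsFactors = FALSE))
  }
  write_tsv(participants, file.path(root, "participants.tsv"))
  cfg <- config
  cfg$cpt_spec <- unclass(cfg$cpt_spec)
  cfg$effect <- unclass(cfg$effect)
  jsonlite::write_json(list(seed = seed, config = unclass(cfg)),
                       file.path(root, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(root)
}
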