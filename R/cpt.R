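#' Specification of one continuous-performance-task block
#'
#' A CPT block is a stream of letter pairs shown on the virtual canvas.
#' Targets are "A" followed by "K"; pseudo-targets are a "K" not preceded
#' by "A" (lures that raise difficulty). The block is partitioned into
#' distractor phases (DP), during which audiovisual distractor events play,
#' and non-distractor phases (NDP).
#'
#' Defaults reproduce the study design: 450 pairs per 18-min block, 135
#' targets, 158 pseudo-targets, 100 ms letters with 1.1 s inter-stimulus
#' interval, three 3-min DP and three 3-min NDP, and 54 distractor events
#' (18 visual, 18 auditory, 18 audiovisual).
#'
#' @param n_pairs Number of letter pairs.
#' @param n_targets Number of A-then-K target pairs.
#' @param n_pseudo Number of pseudo-target pairs (K not after A).
#' @param letter_duration Letter presentation time in seconds.
#' @param isi Inter-stimulus interval in seconds.
#' @param n_dp,n_ndp Number of distractor / non-distractor phases.
#' @param phase_length Phase length in seconds.
#' @param n_distractors Total distractor events per block.
#' @param distractor_modality_counts Named counts for modalities
#'   `visual`, `auditory`, `audiovisual`; must sum to `n_distractors`.
#' @param distractor_duration Duration of each distractor event in seconds.
#' @return An object of class `cpt_block_spec`.
#' @export
cpt_block_spec <- function(n_pairs = 450, n_targets = 135, n_pseudo = 158,
                           letter_duration = 0.1, isi = 1.1,
                           n_dp = 3, n_ndp = 3, phase_length = 180,
                           n_distractors = 54,
                           distractor_modality_counts =
                             c(visual = 18, auditory = 18, audiovisual = 18),
                           distractor_duration = 5) {
  if (n_targets + n_pseudo > n_pairs)
    stop("infeasible spec: n_targets + n_pseudo exceeds n_pairs")
  pair_dur <- 2 * (letter_duration + isi)
  total <- n_pairs * pair_dur
  phase_total <- (n_dp + n_ndp) * phase_length
  if (abs(phase_total - total) > 1e-9)
    stop(sprintf(
      "phases must tile the block: %d phases x %g s = %g s but %d pairs x %g s = %g s",
      n_dp + n_ndp, phase_length, phase_total, n_pairs, pair_dur, total))
  if (sum(distractor_modality_counts) != n_distractors)
    stop("distractor modality counts must sum to n_distractors")
  if (n_dp > 0 && n_distractors %% n_dp != 0)
    stop("n_distractors must divide evenly over DP phases")
  if (n_dp > 0 &&
      (n_distractors / n_dp) * distractor_duration > phase_length)
    stop("distractor events do not fit inside DP phases without overlap")
  structure(list(
    n_pairs = n_pairs, n_targets = n_targets, n_pseudo = n_pseudo,
    letter_duration = letter_duration, isi = isi,
    n_dp = n_dp, n_ndp = n_ndp, phase_length = phase_length,
    n_distractors = n_distractors,
    distractor_modality_counts = distractor_modality_counts,
    distractor_duration = distractor_duration
  ), class = "cpt_block_spec")
}

#' Total duration of a CPT block in seconds
#' @param spec A [cpt_block_spec()].
#' @return Seconds.
#' @export
cpt_block_duration <- function(spec)
  spec$n_pairs * 2 * (spec$letter_duration + spec$isi)

#' Generate one CPT block schedule
#'
#' Builds the letter-pair stream, the DP/NDP phase arrangement and the
#' distractor events for a single block. Pair composition is exact for any
#' seed: `n_targets` pairs (A, K), `n_pseudo` pairs (not-A, K), and the
#' remaining pairs with both letters drawn uniformly from the 24 letters
#' excluding A and K, so no unintended target or lure can arise, within
#' pairs or across pair boundaries. A rejection-resampling pass additionally
#' enforces that no pair ends in "A" directly before a pair starting in "K".
#'
#' @param spec A [cpt_block_spec()].
#' @param rng_seed Integer seed; the schedule is a pure function of
#'   `(spec, rng_seed)`.
#' @return An object of class `cpt_schedule`: list with data.frames
#'   `trials` (pair_index, letter1, letter2, onset1, onset2, is_target,
#'   is_pseudo), `phases` (kind, start, end) and `distractors`
#'   (event_id, modality, onset, duration), plus the `spec`.
#' @export
generate_cpt_block <- function(spec, rng_seed = 1) {
  stopifnot(inherits(spec, "cpt_block_spec"))
  set.seed(rng_seed)
  n_other <- spec$n_pairs - spec$n_targets - spec$n_pseudo
  pool <- setdiff(LETTERS, c("A", "K"))

  l1 <- c(rep("A", spec$n_targets),
          sample(setdiff(LETTERS, "A"), spec$n_pseudo, replace = TRUE),
          sample(pool, n_other, replace = TRUE))
  l2 <- c(rep("K", spec$n_targets + spec$n_pseudo),
          sample(pool, n_other, replace = TRUE))
  is_target <- c(rep(TRUE, spec$n_targets), rep(FALSE, spec$n_pseudo + n_other))
  is_pseudo <- c(rep(FALSE, spec$n_targets), rep(TRUE, spec$n_pseudo),
                 rep(FALSE, n_other))

  ord <- sample.int(spec$n_pairs)
  l1 <- l1[ord]; l2 <- l2[ord]
  is_target <- is_target[ord]; is_pseudo <- is_pseudo[ord]

  # forbid cross-pair A -> K (second letter "A" then first letter "K");
  # impossible under the letter pools above but enforced for custom streams
  for (iter in seq_len(1000)) {
    n <- spec$n_pairs
    bad <- which(l2[-n] == "A" & l1[-1] == "K")
    if (length(bad) == 0) break
    swap <- sample.int(n, length(bad))
    for (k in seq_along(bad)) {
      i <- bad[k]; j <- swap[k]
      for (v in c("l1", "l2", "is_target", "is_pseudo")) {
        tmp <- get(v); t2 <- tmp[i]; tmp[i] <- tmp[j]; tmp[j] <- t2
        assign(v, tmp)
      }
    }
    if (iter == 1000) stop("could not remove cross-pair target sequences")
  }

  step <- spec$letter_duration + spec$isi
  onset1 <- (seq_len(spec$n_pairs) - 1) * 2 * step
  trials <- data.frame(
    pair_index = seq_len(spec$n_pairs),
    letter1 = l1, letter2 = l2,
    onset1 = onset1, onset2 = onset1 + step,
    is_target = is_target, is_pseudo = is_pseudo,
    stringsAsFactors = FALSE
  )

  kinds <- sample(c(rep("DP", spec$n_dp), rep("NDP", spec$n_ndp)))
  n_phase <- spec$n_dp + spec$n_ndp
  phases <- data.frame(
    kind = kinds,
    start = (seq_len(n_phase) - 1) * spec$phase_length,
    end = seq_len(n_phase) * spec$phase_length,
    stringsAsFactors = FALSE
  )

  distractors <- data.frame(event_id = integer(), modality = character(),
                            onset = numeric(), duration = numeric(),
                            stringsAsFactors = FALSE)
  if (spec$n_distractors > 0 && spec$n_dp > 0) {
    modality <- sample(rep(names(spec$distractor_modality_counts),
                           times = spec$distractor_modality_counts))
    per <- spec$n_distractors / spec$n_dp
    d <- spec$distractor_duration
    onsets <- unlist(lapply(which(kinds == "DP"), function(p) {
      slack <- spec$phase_length - per * d
      u <- sort(stats::runif(per, 0, slack))
      phases$start[p] + u + (seq_len(per) - 1) * d
    }))
    distractors <- data.frame(
      event_id = seq_len(spec$n_distractors),
      modality = modality, onset = onsets, duration = d,
      stringsAsFactors = FALSE
    )
  }

  structure(list(trials = trials, phases = phases, distractors = distractors,
                 spec = spec),
            class = "cpt_schedule")
}

#' @export
print.cpt_schedule <- function(x, ...) {
  cat(sprintf(
    "<cpt_schedule> %d pairs (%d targets, %d pseudo), %d phases, %d distractors, %.0f s\n",
    nrow(x$trials), sum(x$trials$is_target), sum(x$trials$is_pseudo),
    nrow(x$phases), nrow(x$distractors), cpt_block_duration(x$spec)))
  invisible(x)
}

schedule_in_dp <- function(schedule, times) {
  dp <- schedule$phases[schedule$phases$kind == "DP", , drop = FALSE]
  res <- rep(FALSE, length(times))
  for (i in seq_len(nrow(dp)))
    res <- res | (times >= dp$start[i] & times < dp$end[i])
  res
}

#' Simulate keypress responses to a CPT schedule
#'
#' Bernoulli responder: each target elicits a keypress with probability
#' `p_hit` at a lognormal latency after the second-letter onset;
#' pseudo-targets and plain non-targets elicit false alarms with
#' probabilities `p_fa_pseudo` / `p_fa_other`. Block-level modulation is
#' multiplicative on the probabilities and on the latency scale.
#'
#' @param schedule A [generate_cpt_block()] schedule.
#' @param profile A [subject_profile()] providing `p_hit`, `p_fa_pseudo`,
#'   `p_fa_other`, `rt_mu`, `rt_sigma` (lognormal parameters in log-ms).
#' @param block_effects Optional list with multipliers `p_hit_mult`,
#'   `p_fa_mult`, `rt_sigma_mult`, additive `rt_mu_shift` (log-ms), and
#'   `dp_p_hit_factor` applied to targets inside distractor phases.
#' @param rng_seed Integer seed.
#' @return data.frame with one row per keypress, column `time` (seconds
#'   from block start), sorted ascending.
#' @export
generate_responses <- function(schedule, profile, block_effects = NULL,
                               rng_seed = 1) {
  stopifnot(inherits(schedule, "cpt_schedule"))
  be <- modifyList(list(p_hit_mult = 1, p_fa_mult = 1, rt_sigma_mult = 1,
                        rt_mu_shift = 0, dp_p_hit_factor = 1),
                   if (is.null(block_effects)) list() else block_effects)
  set.seed(rng_seed)
  tr <- schedule$trials
  p <- numeric(nrow(tr))
  p[tr$is_target] <- min(1, max(0, profile$p_hit * be$p_hit_mult))
  p[tr$is_pseudo] <- min(1, max(0, profile$p_fa_pseudo * be$p_fa_mult))
  p[!tr$is_target & !tr$is_pseudo] <-
    min(1, max(0, profile$p_fa_other * be$p_fa_mult))
  in_dp <- schedule_in_dp(schedule, tr$onset2)
  mod <- tr$is_target & in_dp
  p[mod] <- pmin(1, pmax(0, p[mod] * be$dp_p_hit_factor))

  press <- stats::runif(nrow(tr)) < p
  rt_ms <- stats::rlnorm(sum(press),
                         meanlog = profile$rt_mu + be$rt_mu_shift,
                         sdlog = profile$rt_sigma * be$rt_sigma_mult)
  data.frame(time = sort(tr$onset2[press] + rt_ms / 1000))
}
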