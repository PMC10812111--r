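#' Generate a synthetic gaze label stream
#'
#' Gaze alternates between the task canvas and gaze-wandering as a
#' semi-Markov (alternating renewal) process with exponential dwell times.
#' While a distractor event is active, it captures gaze with probability
#' `p_distract`; the `distractor` label is emitted only during active
#' events, never outside them. Samples are produced at a fixed rate as a
#' label stream, mimicking an area-of-interest hit test.
#'
#' @param schedule A [generate_cpt_block()] schedule supplying the block
#'   duration and distractor events.
#' @param profile A [subject_profile()] supplying `gaze_dwell` (mean dwell
#'   seconds per state) and `p_distract`.
#' @param rng_seed Integer seed.
#' @param rate Sampling rate in Hz (default 50).
#' @param p_distract_mult Multiplier on the capture probability (block
#'   drift).
#' @return data.frame of class `gaze_stream` with columns `time` (s),
#'   `label` (`canvas`, `wander`, `distractor`) and `object_id`
#'   (distractor event id or `NA`).
#' @export
generate_gaze <- function(schedule, profile, rng_seed = 1, rate = 50,
                          p_distract_mult = 1) {
  stopifnot(inherits(schedule, "cpt_schedule"))
  set.seed(rng_seed)
  duration <- cpt_block_duration(schedule$spec)
  dw <- profile$gaze_dwell

  # base alternating canvas/wander process as state intervals
  t <- 0
  starts <- numeric(0); labels <- character(0)
  state <- "canvas"
  while (t < duration) {
    starts <- c(starts, t)
    labels <- c(labels, state)
    mean_dwell <- if (state == "canvas") dw$canvas else dw$wander
    t <- t + if (is.finite(mean_dwell)) stats::rexp(1, 1 / mean_dwell) else
      duration
    state <- if (state == "canvas") "wander" else "canvas"
  }

  times <- seq(0, duration - 1 / rate, by = 1 / rate)
  idx <- findInterval(times, starts)
  label <- labels[idx]
  object_id <- rep(NA_integer_, length(times))

  p_cap <- min(1, max(0, profile$p_distract * p_distract_mult))
  ev <- schedule$distractors
  if (nrow(ev) > 0 && p_cap > 0) {
    captured <- stats::runif(nrow(ev)) < p_cap
    for (k in which(captured)) {
      dwell <- stats::rexp(1, 1 / dw$distractor)
      upper <- ev$onset[k] + min(dwell, ev$duration[k])
      sel <- times >= ev$onset[k] & times < upper
      label[sel] <- "distractor"
      object_id[sel] <- ev$event_id[k]
    }
  }

  structure(data.frame(time = times, label = label, object_id = object_id,
                       stringsAsFactors = FALSE),
            class = c("gaze_stream", "data.frame"))
}
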