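#' Score one CPT block
#'
#' Each keypress is attributed to exactly one letter pair: the pair with the
#' nearest preceding second-letter onset. A target counts as hit when its
#' first attributed keypress falls inside the response window; omission rate
#' is the percentage of targets without a hit. Commission rate is the
#' percentage of non-target pairs (pseudo-targets and plain non-targets
#' pooled) with at least one in-window keypress. Reaction time variability
#' (RTV) is the sample standard deviation of hit reaction times divided by
#' their mean.
#'
#' @param schedule A [generate_cpt_block()] schedule.
#' @param responses data.frame with keypress times in column `time`
#'   (seconds), sorted ascending.
#' @param window Response window after the second-letter onset, in ms
#'   (default `c(150, 1200)`).
#' @return An object of class `cpt_scores`: list with `omission_rate`,
#'   `commission_rate` (percent), `rtv`, `n_hits`, `hit_rts_ms`,
#'   `commission_rate_pseudo`, `commission_rate_other`, `response_window`.
#' @export
score_cpt <- function(schedule, responses, window = c(150, 1200)) {
  stopifnot(inherits(schedule, "cpt_schedule"))
  tr <- schedule$trials
  times <- responses$time
  if (is.unsorted(times)) times <- sort(times)
  win <- window / 1000

  # attribute each keypress to the nearest preceding second-letter onset
  pair <- findInterval(times, tr$onset2)
  valid <- pair >= 1
  rt <- times[valid] - tr$onset2[pair[valid]]
  pair <- pair[valid]
  in_win <- rt >= win[1] & rt <= win[2]

  # first in-window keypress per pair
  first_rt <- rep(NA_real_, nrow(tr))
  hit_pairs <- pair[in_win]
  hit_rts <- rt[in_win]
  if (length(hit_pairs) > 0) {
    ord <- order(hit_pairs, hit_rts)
    keep <- !duplicated(hit_pairs[ord])
    first_rt[hit_pairs[ord][keep]] <- hit_rts[ord][keep]
  }

  responded <- !is.na(first_rt)
  n_targets <- sum(tr$is_target)
  n_nontargets <- sum(!tr$is_target)
  omission <- 100 * sum(tr$is_target & !responded) / n_targets
  commission <- 100 * sum(!tr$is_target & responded) / n_nontargets
  com_pseudo <- if (sum(tr$is_pseudo) > 0)
    100 * sum(tr$is_pseudo & responded) / sum(tr$is_pseudo) else NA_real_
  n_other <- sum(!tr$is_target & !tr$is_pseudo)
  com_other <- if (n_other > 0)
    100 * sum(!tr$is_target & !tr$is_pseudo & responded) / n_other else
      NA_real_

  hit_rts_ms <- 1000 * first_rt[tr$is_target & responded]
  n_hits <- length(hit_rts_ms)
  if (n_hits < 2)
    stop("RTV undefined: fewer than 2 hits")
  rtv <- stats::sd(hit_rts_ms) / mean(hit_rts_ms)

  structure(list(omission_rate = omission, commission_rate = commission,
                 commission_rate_pseudo = com_pseudo,
                 commission_rate_other = com_other,
                 rtv = rtv, n_hits = n_hits, hit_rts_ms = hit_rts_ms,
                 response_window = window),
            class = "cpt_scores")
}

#' @export
print.cpt_scores <- function(x, ...) {
  cat(sprintf(
    "<cpt_scores> omission %.1f%%, commission %.1f%%, RTV %.3f (%d hits)\n",
    x$omission_rate, x$commission_rate, x$rtv, x$n_hits))
  invisible(x)
}

#' Summarize subjective symptom ratings
#'
#' Arithmetic mean of Likert ratings per scale, block and (if present)
#' intervention, across subjects. Values must lie in [-3, 3].
#'
#' @param ratings data.frame with columns `scale`, `block`, `value` and
#'   optionally `intervention` and `subject`.
#' @return data.frame of cell means with column `mean_value`.
#' @export
summarize_ratings <- function(ratings) {
  stopifnot(all(c("scale", "block", "value") %in% names(ratings)))
  if (any(ratings$value < -3 | ratings$value > 3))
    stop("ratings outside [-3, 3]")
  by <- list(scale = ratings$scale, block = ratings$block)
  if ("intervention" %in% names(ratings))
    by$intervention <- ratings$intervention
  agg <- stats::aggregate(ratings$value, by = by, FUN = mean)
  names(agg)[names(agg) == "x"] <- "mean_value"
  agg
}
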