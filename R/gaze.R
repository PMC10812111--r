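#' Dwell-time fractions of a gaze stream
#'
#' Percentage of block samples labeled canvas, distractor and gaze
#' wandering. Samples outside the block window are ignored; samples with a
#' missing label (lost tracking) are counted as wandering.
#'
#' @param stream A [generate_gaze()] stream (columns `time`, `label`).
#' @param block_window Two-element window in seconds; default spans the
#'   whole stream.
#' @return An object of class `gaze_summary`: list with `pct_canvas`,
#'   `pct_distractor`, `pct_wander`, `n_samples`.
#' @export
dwell_fractions <- function(stream, block_window = NULL) {
  stopifnot(all(c("time", "label") %in% names(stream)))
  if (is.null(block_window))
    block_window <- c(min(stream$time), max(stream$time) + 1e-9)
  sel <- stream$time >= block_window[1] & stream$time < block_window[2]
  if (!any(sel)) stop("no gaze samples inside the block window")
  lab <- stream$label[sel]
  lab[is.na(lab) | !lab %in% c("canvas", "distractor", "wander")] <- "wander"
  n <- length(lab)
  structure(list(
    pct_canvas = 100 * sum(lab == "canvas") / n,
    pct_distractor = 100 * sum(lab == "distractor") / n,
    pct_wander = 100 * sum(lab == "wander") / n,
    n_samples = n
  ), class = "gaze_summary")
}

#' Composite distractibility score
#'
#' `(pct_distractor + pct_wander) / pct_canvas`; higher values indicate more
#' distraction. With zero canvas time the score is undefined and returned
#' as `NA` with a warning rather than infinity.
#'
#' @param summary A [dwell_fractions()] result (or any list with the three
#'   percentage fields).
#' @return Unitless non-negative scalar, or `NA` when canvas time is zero.
#' @export
distractibility_score <- function(summary) {
  if (summary$pct_canvas <= 0) {
    warning("zero canvas time: distractibility undefined, returning NA")
    return(NA_real_)
  }
  (summary$pct_distractor + summary$pct_wander) / summary$pct_canvas
}
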