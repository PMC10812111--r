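#' Generate a synthetic head-tracking stream
#'
#' Head position (mm) and rotation (deg) follow independent mean-reverting
#' (Ornstein-Uhlenbeck) random walks per axis, scaled by the subject's
#' restlessness; the post-intervention block is scaled by the effect
#' specification's restlessness multiplier, emulating growing restlessness
#' with time on task.
#'
#' @param profile A [subject_profile()].
#' @param effect An [effect_spec()] or `NULL`.
#' @param session List with `intervention` and `block` (the multiplier is
#'   applied when `block == "post"`).
#' @param duration Length in seconds.
#' @param rate Sampling rate in Hz (default 90).
#' @param rng_seed Integer seed.
#' @return data.frame of class `head_track` with columns `time`, `x`, `y`,
#'   `z` (mm) and `yaw`, `pitch`, `roll` (deg).
#' @export
generate_head_track <- function(profile, effect = NULL,
                                session = list(intervention = "sham",
                                               block = "pre"),
                                duration = 1080, rate = 90, rng_seed = 1) {
  set.seed(rng_seed)
  n <- round(duration * rate)
  dt <- 1 / rate
  mult <- if (!is.null(effect) && identical(session$block, "post"))
    effect$restlessness_post_mult else 1

  ou <- function(scale, theta = 0.8) {
    x <- numeric(n)
    eps <- stats::rnorm(n, sd = scale * sqrt(dt))
    for (i in 2:n) x[i] <- x[i - 1] * (1 - theta * dt) + eps[i]
    x
  }
  s_pos <- profile$restlessness * mult
  s_rot <- profile$rot_restlessness * mult
  structure(data.frame(
    time = (seq_len(n) - 1) * dt,
    x = ou(s_pos), y = ou(s_pos), z = 1100 + ou(s_pos),
    yaw = ou(s_rot), pitch = ou(s_rot), roll = ou(s_rot)
  ), class = c("head_track", "data.frame"))
}
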