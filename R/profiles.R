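#' Default posterior-dominant alpha topography
#'
#' Unitless per-channel weights for the alpha oscillator, largest over
#' parieto-occipital sites and fading toward frontal sites, mimicking the
#' posterior dominance of resting alpha.
#'
#' @return Named numeric vector over the 22-channel montage.
#' @export
default_alpha_gain <- function() {
  g <- c(Fp1 = 0.15, Fp2 = 0.15, AFz = 0.18, F3 = 0.22, Fz = 0.22, F4 = 0.22,
         T7 = 0.3, C3 = 0.4, Cz = 0.45, C4 = 0.4, T8 = 0.3,
         CPz = 0.7, P7 = 0.6, P3 = 0.75, Pz = 1.0, P4 = 0.75, P8 = 0.6,
         POz = 0.95, O1 = 0.85, O2 = 0.85, M1 = 0.25, M2 = 0.25)
  g[montage_channels()]
}

#' Construct a synthetic subject profile
#'
#' Bundles every subject-level parameter of the generators: the individual
#' alpha frequency (IAF) and oscillator amplitude, background-noise shape,
#' blink rate, the CPT responder model, gaze dwell means and head
#' restlessness. Defaults describe a plausible adult participant with the
#' cohort-mean IAF near 9.6 Hz.
#'
#' @param iaf Individual alpha frequency in Hz (7-13).
#' @param alpha_amp Alpha oscillator amplitude in microvolts (peak scale).
#' @param alpha_bw Full width at half maximum of the alpha spectral peak, Hz.
#' @param alpha_gain Named per-channel topography weights.
#' @param one_over_f_exponent Spectral exponent of the 1/f background.
#' @param noise_rms Broadband background RMS amplitude in microvolts.
#' @param blink_rate Blink events per minute.
#' @param p_hit Probability of responding to a target.
#' @param p_fa_pseudo,p_fa_other False-alarm probabilities for pseudo-target
#'   and plain non-target pairs.
#' @param rt_mu,rt_sigma Lognormal reaction-time parameters in log-ms.
#' @param gaze_dwell Named list of mean dwell durations in seconds for
#'   states `canvas`, `wander`, `distractor`.
#' @param p_distract Probability that an active distractor event captures
#'   gaze.
#' @param restlessness Head-position random-walk scale, mm per sqrt(s).
#' @param rot_restlessness Head-rotation random-walk scale, deg per sqrt(s).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(iaf = 9.6, alpha_amp = 10, alpha_bw = 0.4,
                            alpha_gain = default_alpha_gain(),
                            one_over_f_exponent = 1, noise_rms = 10,
                            blink_rate = 8,
                            p_hit = 0.85, p_fa_pseudo = 0.06,
                            p_fa_other = 0.01,
                            rt_mu = log(450), rt_sigma = 0.25,
                            gaze_dwell = list(canvas = 20, wander = 4,
                                              distractor = 3),
                            p_distract = 0.5,
                            restlessness = 6, rot_restlessness = 3) {
  if (iaf < 7 || iaf > 13) stop("iaf must lie in [7, 13] Hz")
  if (alpha_amp < 0) stop("alpha_amp must be >= 0")
  probs <- c(p_hit = p_hit, p_fa_pseudo = p_fa_pseudo,
             p_fa_other = p_fa_other, p_distract = p_distract)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  structure(list(
    iaf = iaf, alpha_amp = alpha_amp, alpha_bw = alpha_bw,
    alpha_gain = alpha_gain,
    one_over_f_exponent = one_over_f_exponent, noise_rms = noise_rms,
    blink_rate = blink_rate,
    p_hit = p_hit, p_fa_pseudo = p_fa_pseudo, p_fa_other = p_fa_other,
    rt_mu = rt_mu, rt_sigma = rt_sigma,
    gaze_dwell = gaze_dwell, p_distract = p_distract,
    restlessness = restlessness, rot_restlessness = rot_restlessness
  ), class = "subject_profile")
}

#' Construct an intervention effect specification
#'
#' Defines the condition structure injected by the generators across the
#' 2 (intervention: active, sham) x 2 (block: pre, post) design. Alpha
#' amplitude in the post block is the pre-block amplitude times the
#' per-intervention multiplier; behavioral, gaze, actigraphy and rating
#' drifts apply to the post block of both interventions (time-on-task
#' effects). Defaults encode a strong pre-to-post alpha increase under both
#' interventions, larger under active stimulation, plus post-block increases
#' in head movement and distractor gaze and a small drop in reported
#' hyperactivity.
#'
#' @param pre_post_multiplier_sham,pre_post_multiplier_active Multiplicative
#'   change of alpha amplitude from the pre to the post block (> 0).
#' @param log_alpha_subject_sd Between-subject SD of the log10 amplitude
#'   multipliers.
#' @param omission_post_mult,commission_post_mult Multipliers on miss /
#'   false-alarm probabilities in the post block.
#' @param distractor_gaze_post_mult Multiplier on the gaze-capture
#'   probability in the post block.
#' @param restlessness_post_mult Multiplier on head restlessness in the post
#'   block.
#' @param rating_post_shift Named additive shifts (Likert units) for scales
#'   `inattention`, `hyperactivity`, `impulsivity` in the post block.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(pre_post_multiplier_sham = 1.5,
                        pre_post_multiplier_active = 2.0,
                        log_alpha_subject_sd = 0.05,
                        omission_post_mult = 1.1,
                        commission_post_mult = 1.1,
                        distractor_gaze_post_mult = 1.3,
                        restlessness_post_mult = 1.33,
                        rating_post_shift = c(inattention = 0,
                                              hyperactivity = -0.16,
                                              impulsivity = 0)) {
  if (pre_post_multiplier_sham <= 0 || pre_post_multiplier_active <= 0)
    stop("pre/post multipliers must be > 0")
  structure(list(
    pre_post_multiplier_sham = pre_post_multiplier_sham,
    pre_post_multiplier_active = pre_post_multiplier_active,
    log_alpha_subject_sd = log_alpha_subject_sd,
    omission_post_mult = omission_post_mult,
    commission_post_mult = commission_post_mult,
    distractor_gaze_post_mult = distractor_gaze_post_mult,
    restlessness_post_mult = restlessness_post_mult,
    rating_post_shift = rating_post_shift
  ), class = "effect_spec")
}

#' Alpha amplitude multiplier for one design cell
#'
#' @param effect An [effect_spec()] (or `NULL` for no effect).
#' @param intervention `"active"` or `"sham"`.
#' @param block `"pre"`, `"during"` or `"post"`.
#' @return Scalar multiplier applied to the subject's alpha amplitude.
#' @export
alpha_multiplier <- function(effect, intervention, block) {
  if (is.null(effect) || block %in% c("pre", "during")) return(1)
  if (block != "post") stop("unknown block: ", block)
  switch(intervention,
         active = effect$pre_post_multiplier_active,
         sham = effect$pre_post_multiplier_sham,
         stop("unknown intervention: ", intervention))
}
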