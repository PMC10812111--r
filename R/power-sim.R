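# Summary-level cohort simulation. The full generators produce raw streams;
# for replicate-heavy calibration studies (type-I error, empirical power)
# the same 2x2 condition structure is drawn directly at the level of the
# per-cell summary statistic, which is the quantity the ANOVA consumes.

#' Simulate a 2x2 condition table at the summary level
#'
#' Cell values follow `value = subject_intercept + block_shift +
#' interaction_shift * (post & active) + noise`, the additive (log-scale)
#' structure the raw-EEG generator induces in mean alpha power: a common
#' pre-to-post shift plus an extra shift under active stimulation.
#'
#' @param n_subjects Number of subjects.
#' @param block_shift Common post-minus-pre shift (both interventions).
#' @param interaction_shift Additional post-block shift under active
#'   stimulation.
#' @param subject_sd SD of subject intercepts.
#' @param cell_sd SD of independent per-cell noise.
#' @param rng_seed Integer seed.
#' @return A [condition_table()].
#' @export
simulate_condition_table <- function(n_subjects = 15, block_shift = 0,
                                     interaction_shift = 0,
                                     subject_sd = 0.5, cell_sd = 0.1,
                                     rng_seed = 1) {
  set.seed(rng_seed)
  subs <- sprintf("sub-%02d", seq_len(n_subjects))
  grid <- expand.grid(subject = subs,
                      intervention = c("active", "sham"),
                      block = c("pre", "post"),
                      stringsAsFactors = FALSE)
  intercept <- stats::rnorm(n_subjects, 3.1, subject_sd)
  names(intercept) <- subs
  mu <- intercept[grid$subject] +
    block_shift * (grid$block == "post") +
    interaction_shift * (grid$block == "post" &
                           grid$intervention == "active")
  condition_table(grid$subject, grid$intervention, grid$block,
                  mu + stats::rnorm(nrow(grid), 0, cell_sd))
}

#' Interaction shift matching a target partial eta squared
#'
#' Inverts the noncentrality convention of [interaction_power()]: chooses
#' the `interaction_shift` for [simulate_condition_table()] such that the
#' simulated interaction test has noncentrality
#' `lambda = f^2 * N * m * epsilon / (1 - rho)` with
#' `f^2 = eta_p_sq / (1 - eta_p_sq)`. With independent per-cell noise of SD
#' `cell_sd`, the per-subject interaction contrast (difference of
#' differences) has SD `2 * cell_sd` and the paired test on it has
#' noncentrality `N * (shift / (2 * cell_sd))^2`.
#'
#' @param eta_p_sq Target partial eta squared.
#' @param n_subjects Number of subjects.
#' @param cell_sd Per-cell noise SD used by the simulator.
#' @param m,rho,epsilon Conventions of [power_spec()].
#' @return The interaction shift (same units as the summary statistic).
#' @export
calibrate_interaction_shift <- function(eta_p_sq, n_subjects,
                                        cell_sd = 0.1, m = 2, rho = 0.5,
                                        epsilon = 1) {
  f2 <- eta_p_sq / (1 - eta_p_sq)
  lambda <- f2 * n_subjects * m * epsilon / (1 - rho)
  2 * cell_sd * sqrt(lambda / n_subjects)
}

#' Empirical rejection rate of the interaction test
#'
#' Simulates replicate cohorts with [simulate_condition_table()] and
#' reports how often the 2x2 ANOVA rejects the interaction null.
#'
#' @param n_replicates Number of replicate cohorts.
#' @param alpha Test level.
#' @param rng_seed Base seed; replicate r uses `rng_seed + r`.
#' @param ... Passed to [simulate_condition_table()].
#' @return Rejection fraction in [0, 1].
#' @export
interaction_rejection_rate <- function(n_replicates = 100, alpha = 0.05,
                                       rng_seed = 1, ...) {
  rej <- vapply(seq_len(n_replicates), function(r) {
    tab <- simulate_condition_table(rng_seed = rng_seed + r, ...)
    res <- rm_anova_2x2(tab)
    res$p[res$effect == "Interaction"] < alpha
  }, logical(1))
  mean(rej)
}
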