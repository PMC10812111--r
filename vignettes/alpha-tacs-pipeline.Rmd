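---
title: "Simulating and analyzing crossover alpha-tACS studies"
author: "alphacross"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphacross)
```

## The study design this package models

`alphacross` implements the full measurement and analysis chain of a
sham-controlled crossover trial of individual-alpha-frequency transcranial
alternating current stimulation (tACS) during a sustained-attention task.
Each subject completes two sessions (active stimulation, sham stimulation;
order counterbalanced across subjects). A session contains three blocks of
a letter continuous performance task (CPT) separated by short resting EEG
phases; stimulation is applied during the middle block, so the pre- and
post-intervention blocks carry the outcome measures. Every outcome is
analyzed with a 2 (Block: pre, post) x 2 (Intervention: active, sham)
within-subject ANOVA; the Block x Intervention interaction is the effect of
interest, because a genuine stimulation after-effect must show up as a
*larger* pre-to-post change under active than under sham stimulation.

No public data exist for this design, so the package pairs every analysis
stage with a generator that synthesizes the corresponding raw stream (EEG,
keypresses, gaze labels, head tracking, stimulation current). The
generators are first-class, tested code: their outputs are written to disk
in the formats a real laboratory would use (EDF for EEG, tab-separated
event tables for everything else) and the analysis side only ever reads
those files.

## The synthetic cohort

### Subjects and effects

A `subject_profile()` collects the per-subject parameters: the individual
alpha frequency (IAF, drawn near the population mean of 9.65 Hz when
cohorts are generated), the alpha oscillator amplitude in microvolts, the
spectral exponent and RMS of the 1/f background, blink rate, the CPT
responder model (hit probability, false-alarm probabilities for lures and
plain non-targets, lognormal reaction-time parameters), gaze dwell means,
and head restlessness.

An `effect_spec()` injects the condition structure. Alpha amplitude in the
post block equals the pre-block amplitude times a per-intervention
multiplier; the defaults (sham 1.5, active 2.0) encode a strong
time-on-task alpha increase under both interventions with a larger increase
under active stimulation, i.e. a Block main effect plus a
Block x Intervention interaction on log alpha power, the structure the
statistics module is built to detect. On the log10 power scale an amplitude
multiplier m contributes 2 log10(m), so the default interaction amounts to
2(log10 2 - log10 1.5) = 0.25 log10 units. Time-on-task drifts for the
other modalities (more head movement, more distractor-directed gaze, small
rating shifts post-intervention) are also part of `effect_spec()`.

### EEG

`generate_eeg()` builds each channel as a sum of three components, in
microvolts:

* **1/f background.** Constructed in the frequency domain with amplitude
  proportional to f^(-beta/2) and random phases. A fraction of this
  background (amplitude weight `noise_share = 0.75`) is shared across all
  channels, the rest is channel-specific. The sharing mimics volume
  conduction, which makes real scalp channels strongly correlated; the
  artifact-rejection stage behaves realistically only on such correlated
  data (see below).
* **Alpha oscillator.** A single narrowband source (Gaussian spectral bump
  at the IAF, 0.4 Hz full width at half maximum) multiplied by a fixed
  posterior-dominant topography: weight 1.0 at Pz, ~0.9 at POz/O1/O2,
  fading to ~0.2 frontally. One shared source for all channels is a
  deliberate simplification of a posterior alpha generator.
* **Blinks.** Poisson events (default 8/min) with a 350 ms raised-cosine
  time course, ~120 uV at Fp1/Fp2 and decaying rapidly toward posterior
  sites.

The during-stimulation block additionally receives a sinusoidal tACS
artifact at the IAF (default 2000 uV) shaped by the stimulation envelope,
so the pipeline's "drop the during-stimulation block" rule operates on
data that would genuinely be unusable.

### Task, gaze, head tracking, stimulation

`generate_cpt_block()` produces the letter stream as explicit pairs: 450
pairs per block, 135 targets (A then K), 158 pseudo-targets (K not
preceded by A) and 157 remaining pairs whose letters are drawn uniformly
from the 24 letters excluding A and K. Drawing the filler letters from
that restricted pool guarantees, by construction, that no unintended
target or lure can arise either within or across pairs; an explicit
rejection-resampling pass additionally verifies the cross-pair rule for
customized streams. Letters last 100 ms with a 1.1 s inter-stimulus
interval, so a block lasts exactly 1080 s. The block is tiled by three
3-min distractor phases (DP) and three 3-min non-distractor phases in a
seeded random arrangement; 54 distractor events (18 visual, 18 auditory,
18 audiovisual) are placed uniformly at random inside the DP windows
subject to non-overlap, with a 5 s default duration (event durations and
spacing are not constrained by the design, so these are package choices).

`generate_responses()` is a Bernoulli responder with lognormal latencies.
`generate_gaze()` alternates canvas and wandering dwells as an alternating
renewal process with exponential dwell times; an active distractor event
captures gaze with probability `p_distract`, and the `distractor` label
can occur only while an event is active. `generate_head_track()` uses
mean-reverting (Ornstein-Uhlenbeck) random walks per axis for position
(mm) and rotation (deg). `generate_stim_waveform()` produces the active
protocol (18 min sinusoid at the IAF, 1.5 mA peak, 10 s linear ramps) and
the sham protocol (10 s fade-in, 10 s plateau, 10 s fade-out; 30 s total).

`generate_cohort()` writes the whole study to disk as
`sub-XX/ses-{active,sham}/` with EDF EEG per block and resting phase plus
TSV streams, fully reproducible from `(config, seed)`.

## The analysis chain

### Individual alpha frequency

`iaf_from_rest()` reproduces the on-site procedure: blink removal, then
channel Pz alone is band-passed 0.1-40 Hz (zero phase), cut into 2 s
epochs, cleaned by the joint-probability test at 1.7 SD, and the averaged
log10 periodogram — zero-padded to a 0.05 Hz grid — is maximized over the
closed 7-13 Hz band (ties break toward the lower edge). Working on the
single spectral channel matters: applying the any-channel rejection union
to all 22 channels discards many clean Pz epochs and measurably inflates
the peak-estimate jitter.

Blink removal is an automated substitute for visual independent-component
curation: the 0.5-4 Hz band-passed mean of Fp1/Fp2 is regressed out of
every channel. The reference carries no alpha-band energy, so alpha
activity cannot be removed by construction — the property the original
manual curation protected by retaining components with a 10 Hz peak.

### Artifact handling for the wavelet analysis

The improbability statistic is the mean negative log probability of an
epoch's samples under the channel's empirical amplitude distribution
(100-bin histogram, add-one smoothing, fitted across all epochs). An epoch
is rejected when any channel's statistic exceeds its across-epoch mean by
more than k SDs, or the all-channel mean statistic does. Rejection is
one-sided: the test removes *improbable* epochs; an epoch that is unusually
typical is not an artifact. Because the rule takes a union over channels,
its false-rejection rate depends strongly on inter-channel correlation:
on hypothetical *independent* channels it would reject roughly half of
perfectly clean 22-channel data, while on realistically correlated
channels (shared sources) survival is high. This is the main reason the
generator's background is spatially shared.

`clean_epochs()` then applies, in order: the joint-probability test at
2 SD; marking of channels exceeding 150 uV per epoch; exclusion of
channels marked in more than 15% of epochs; rejection of epochs with more
than 10 marked channels; spherical-spline interpolation of the remaining
marked channels. Continuous recordings are first resampled to 250 Hz
(polyphase FIR), band-passed 1-40 Hz (zero-phase Butterworth; second-order
high-pass cascaded with a sixth-order low-pass, which keeps the 0.004 s
grid and attenuates 60 Hz to below 1% amplitude) and linearly detrended.
Bad channels in the continuous data are flagged by a robust z-score of the
log channel variance (|z| > 3 on the median/MAD scale) — the detection
criterion itself is a package choice, since "noisy channels were detected"
does not pin one down — and repaired with Perrin-style spherical splines
(stiffness m = 4, 50 Legendre terms, ridge 1e-8) on an idealized
unit-sphere 10/20 montage.

### Morlet alpha power

The continuous wavelet transform uses an analytic Morlet wavelet with a
fixed width of 3 cycles (at 10 Hz the Gaussian envelope then spans roughly
three oscillation periods), evaluated by FFT convolution at 69
log-spaced frequencies from 0.27 to 30.00 Hz on 2 s epochs at 250 Hz. The
wavelet envelope is normalized to unit DC gain, so a unit-amplitude
sinusoid at a grid frequency yields power 0.25 there — the closed form the
test suite checks to within 2%. At the lowest grid frequencies the wavelet
support exceeds the epoch, so those coefficients are edge-dominated; the
alpha summaries never touch them, as they average 7-13 Hz over
0.2-1.8 s within the epoch and the five centro-parietal channels (Pz,
POz, CPz, P3, P4).

Power is averaged across epochs *before* the log10 transform by default.
The alternative order (log per epoch, then average) is exposed via
`log_each_epoch = TRUE`; the two differ on variable data by Jensen's
inequality, and the default was fixed once so that downstream numbers are
reproducible. Silent input is kept finite by a power floor of 1e-12 before
the logarithm. Per intervention, subjects whose post-minus-pre alpha
change deviates more than 2 SD from the mean change are flagged
(`flag_alpha_outliers()`).

### Behavioral, gaze and actigraphy scoring

`score_cpt()` attributes each keypress to the pair with the nearest
preceding second-letter onset and accepts it within a 150-1200 ms window
(the task's 1.2 s letter cycle bounds the window above; 150 ms excludes
anticipations; the window is configurable because the original scoring
window is not documented). Omission rate is the percentage of targets
without an accepted response; commission rate pools pseudo-targets and
plain non-targets (subtype rates are also emitted); reaction-time
variability is the sample (n-1) SD of hit reaction times divided by their
mean, and is an error below two hits. `dwell_fractions()` and
`distractibility_score()` compute the gaze percentages and the composite
(distractor% + wander%) / canvas%, returning a missing value with a
warning when canvas time is zero rather than an infinity. Lost-tracking
samples count as wandering (configurable interpretation). Head tracking is
decimated to 10 Hz by nearest-sample selection — averaging would shrink
step distances — and summarized as the mean consecutive-sample Euclidean
distance of the 3-vector; rotation differences are wrapped to
(-180, 180] per axis first, so trajectories crossing the +-180 seam do
not produce near-360 degree artifacts.

### Statistics and power

`rm_anova_2x2()` is the classical univariate decomposition: each effect is
tested against its effect-by-subject stratum, F = MS_effect /
MS_(effect x subject) with df (1, n-1), and partial eta squared is
SS_effect / (SS_effect + SS_error). The four follow-up contrasts (sham
pre/post, active pre/post, pre active/sham, post active/sham) are paired
two-sided t tests flagged against the Bonferroni threshold 0.05/4 =
0.0125.

`interaction_power()` follows the conventional repeated-measures
within-between template: f^2 = eta_p^2 / (1 - eta_p^2), noncentrality
lambda = f^2 N m epsilon / (1 - rho) with m repeated measurements,
repeated-measures correlation rho (default 0.5) and nonsphericity epsilon
(default 1; a 2 x 2 design needs no correction), df = (g-1)(m-1) and
(N-g)(m-1) epsilon, and power is the upper tail of the noncentral F beyond
the central critical value. At eta_p^2 = 0.23 and N = 15 this yields
97.4%. That template is, strictly, a between-groups design template
applied to a fully-within crossover; the package mirrors that stated
analysis choice rather than correcting it. `required_sample_size()`
searches the smallest N reaching a target power; under these conventions
the minimum for eta_p^2 = 0.14 at 80% power is N = 15, while entering
f^2 = eta^2 directly — a different effect-size-specification convention
offered by common power software — gives N = 16. The package reports its
value together with the assumption set instead of forcing one convention
to agree with the other.

### Calibration studies

For replicate-heavy questions (type-I error of the interaction test,
empirical power against the analytic prediction)
`simulate_condition_table()` draws cohorts directly at the level of the
per-cell summary statistic, with the same additive structure the raw-EEG
generator induces in log10 alpha power: subject intercept + common
pre-to-post shift + extra active-post shift + independent cell noise.
`calibrate_interaction_shift()` inverts the power convention above so a
requested eta_p^2 maps onto the simulated noncentrality exactly
(per-subject interaction contrast SD is 2 cell_sd, so lambda =
N (shift / (2 cell_sd))^2). The equivalence between the raw-EEG route and
the summary-level route is pinned separately by a test that recovers an
injected amplitude multiplier m as a 2 log10(m) change in the Morlet
alpha summary.

## Problem sizes and reproducibility

The default `cohort_config()` is a scaled-down study: the full 450-pair
CPT schedules, gaze and head-track streams (counts are never scaled), but
3-min EEG per block and 2-min resting phases; `full_scale = TRUE`
restores 18-min EEG blocks. The test suite exercises the complete chain
on micro cohorts (25-pair schedules, 20 s EEG) and the statistical
calibrations on 300-400 summary-level replicate cohorts; the
end-to-end IAF recovery check spans 50 subjects at the generator's
default signal-to-noise ratio. Every generator is a pure function of its
parameters and an integer seed, and identical `(config, seed)` pairs
produce byte-identical files on disk.

## What passing tests do and do not show

The generators emulate the *statistical structure* the analysis assumes:
narrowband posterior alpha over a correlated 1/f background, blink-like
frontal transients, Bernoulli/lognormal responding, renewal-process gaze
and Ornstein-Uhlenbeck head motion. They do not emulate non-stationary
artifact regimes (electrode drift, movement bursts, sweating), true
oscillatory bursting, heartbeat or line noise, saccade dynamics, or any
entrainment physics of tACS itself — the "active" effect is injected as an
amplitude multiplier, not produced by a neural model. Passing tests
therefore certify that the pipeline recovers known injected structure
under realistic noise, not that it would make identical decisions on any
particular real recording.

## Known limitations

* The EDF writer targets the continuous subset used here (one shared
  integer sampling rate, 1 s records); it is not a general EDF+ library.
* The histogram-based improbability test is an operational re-specification
  of a toolbox builtin; absolute rejection rates differ between
  implementations even though both order epochs the same way.
* The idealized spherical montage ignores individual head geometry, which
  is acceptable for interpolation but not for source-level claims.
* With a 2 s epoch and a 0.05 Hz zero-padded grid, neighboring spectral
  bins are strongly interpolated; the 0.05 Hz resolution is a grid
  spacing, not an independent-frequency resolution.
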