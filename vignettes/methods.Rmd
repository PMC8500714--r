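---
title: "Models, statistics and design choices in stnreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics and design choices in stnreach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the package's scientific model, the parameters that
matter, what the synthetic generator does and does not emulate, and the
design choices made where the method left room. It states no empirical
result beyond what the test suite and the acceptance script compute.

## The problem

Intraoperative STN recordings during reaching are short (minutes), have
few trials per condition (roughly 4–47), mix single units, multi-units
and background hash, and have trial events at variable latencies. The
analysis chain must therefore (i) respect trial-to-trial event jitter
when averaging, (ii) control family-wise error over time without
pre-registering analysis windows, and (iii) measure spike–field coupling
with an estimator that is unbiased under firing-rate differences. These
three constraints drive most of the machinery here.

## Synthetic sessions: the stated world

`task_config()` encodes the task: initial Reach cue probability 0.65
(within the 60–70% design range), half of initially-Reach trials
converted to Impromptu Turns, fixation delay truncated-exponential on
[300, 600] ms with mean 400 ms, go delay on [400, 1000] ms with mean
600 ms, turn-cue window centre uniform over 35–65% of the
fixation-to-target distance, and a 1.5 s inter-trial interval. The
truncated-exponential rate is solved numerically so the analytic
truncated mean equals the target (feasible only for means strictly
between the lower bound and the range midpoint, since the truncated
density is decreasing).

Values the task description leaves open were fixed once at what typical
reaching studies report and not revisited:

* movement-onset latency from the go cue: Gaussian, mean 250 ms, SD
  40 ms, truncated at 100 ms;
* impromptu turn latency from the turn cue: mean 330 ms, SD 50 ms —
  deliberately longer than the movement latency, matching the observed
  ordering of those latencies;
* horizontal reach: minimum-jerk, 700 ms over 10 screen units; planned
  corners are reached by a minimum-jerk segment whose duration scales
  with distance (so peak speed matches reaches); vertical segments are
  minimum-jerk, 550 ms over 6 units (slower than the reach peak, so
  speed-based movement detection locks onto the reach);
* cursor position noise: 0.005 units SD per 100 Hz sample (≈0.05% of the
  reach extent — optical-tracker scale).

Spikes are an inhomogeneous Poisson process (thinning against a grid-based
intensity ceiling with 10% margin) with intensity

    λ(t) = max(0, [b + β₁ v_z(t+Δt) + β₂ a_z(t+Δt) + offset(t)]
                  · g_type · g_dir(t) · [1 + m·cos φ_β(t)])

Clipping at zero is part of the generative model. The medial/lateral
direction gain is active only in a [−10, +270] ms window around movement
onset, mirroring where direction information is reported in this
literature. The LFP is 1/f^χ Gaussian background (χ = 1.5) plus a 20 Hz
carrier with deterministic phase whose amplitude envelope drops by a
configurable factor (default 0.5) between each movement onset and
feedback, with 100 ms raised-cosine ramps; the exact phase and envelope
are returned as ground truth so spike phase-locking and beta suppression
are both verifiable.

What the generator does **not** emulate: non-Poisson spiking statistics
(bursting, refractoriness), non-stationary baselines, drifting units,
correlated noise across units, realistic Parkinsonian pathophysiology,
artifacts other than amplitude outliers, or biomechanics. A green test
therefore establishes correctness of the *analysis* under a matched
generative model, not robustness to every property of patient data.

### Operational event ground truth

The field defines movement onset as "the acceleration peak most closely
preceding peak cursor speed" — an operational definition that does not
coincide with the latent motion-start time of a minimum-jerk segment
(the acceleration peak falls ~21% into the segment). The trial table
therefore records the *operational* events, obtained by running the
detectors on the noise-free closed-form trajectory; latent motion-start
times remain available in `ground_truth$latent_events`. Detector tests
then measure noise robustness, which is the meaningful claim.

Two detector details deviate from the simplest reading of the rule, for
robustness: candidate acceleration peaks must reach 50% of the window
maximum (a bare "latest local maximum" rule latches onto noise bumps next
to the speed peak), and the movement heading is smoothed (30 ms Gaussian)
after unwrapping and speed-masking (floor: 5% of peak speed) before the
angular acceleration is differenced — raw second differences of heading
at 100 Hz are noise-dominated at any realistic tracker noise.

## PSTHs and censoring

Rates use the causal alpha kernel α²τe^(−ατ), α = 20 s⁻¹ (unit mass,
peak 1/α after each spike). Spikes are censored outside the open interval
between the alignment event's neighbours and within 500 ms of the
previous trial's end; censoring is tracked per time point so averages and
standard errors use only valid trials — censored stretches are NA, never
zero. `aligned_trial_rates(warmup_s=)` optionally drops ~3/α after each
censoring bound, where the causal kernel is still ramping up; the lagged
regression uses this, displays do not (matching common practice).

The pooled-sample standard deviation over all per-trial rate samples is
used to z-score response profiles ("across all trials" is ambiguous
between pooled samples and per-trial means; pooled is the default, and
the profile machinery flags zero-SD units instead of dividing by zero).

## The extended cluster-mass framework

Pointwise repeated-measures F statistics are thresholded at the 90th
percentile of the corresponding F distribution; maximal contiguous
supra-threshold runs become clusters scored by their summed SS_error
(options: SS_M, F); the null is the distribution of the maximum cluster
score under permutation of the tested factor's labels within each unit;
p = (1 + #{null ≥ obs}) / (1 + n_perm), so p is never zero and its
resolution is 1/(n_perm+1). Units with a missing cell at a time point are
dropped from that time point only.

A property of the SS_error cluster score worth knowing: for *very large*
homogeneous effects, permutation moves the effect variance into SS_error,
inflating the null maxima and costing power (the observed cluster must
win through extent). At realistic effect sizes (≲2 SD) the test behaves
well; the two-factor variant exposes a sum-of-F cluster score as an
option for the homogeneous-effect situation. FWER calibration under
exchangeable nulls is part of the acceptance suite (bound 7% at nominal
5% over 500 smoothed-noise populations).

For the multidimensional (PC-space) variant there are no repeated
measures, so sums of squared Euclidean distances from the condition
centroid replace F; the pointwise threshold is the 90th percentile of the
permutation distribution of that sum at each time point, permuted unit
means are re-projected onto the *original* components, and cluster scores
are within-cluster sums. Pairwise follow-ups use the time-averaged
squared distance in a window; subtracting each null value from the
observed statistic yields the distribution whose mean and 2.5/97.5
percentiles are reported as distance-above-chance with CI.

The trial-level (single-unit) test uses the standard weighted
between-trials sum of squares Σₘ Nₘ(r̄ₘ−r̄)², which satisfies F = t² for
two conditions. The printed form of the source equation omits the Nₘ
weight; the weighted form is the one consistent with the F = t² oracle.

Unit counting uses the upper-tail binomial at 10% chance
(P(X ≥ k | n, 0.1)); Holm–Bonferroni is the classic step-down with
monotonicity enforcement.

## Lagged kinematic regression

One OLS per unit of the type-mean rate on lagged type-mean z-scored speed
and acceleration, pooled over types, with the fit restricted to
[t_start − Δt_min, t_end − Δt_max] so the fitted points are identical for
every lag and unit; points outside that range but inside the data span at
the best lag are the held-out test set. Weighted least squares with the
per-sample valid-trial count as weight accounts for censoring-induced
heteroscedasticity at window edges.

Two numerical choices matter for unbiased lag recovery:

* **Kernel-matched filtering.** The kinematic regressors are filtered
  with the same causal alpha kernel used for the rates (point-sampled to
  12/α so the discrete centroid matches the continuous 2/α within a
  fraction of a millisecond). Identical filtering on both sides leaves
  the lag estimate of a linear rate model unbiased; without it the
  kernel's 100 ms mean delay shifts every recovered lag.
* **Grid margin.** The recovery harness searches ±250 ms in 10 ms steps
  rather than ±200 ms: when the largest true lag sits one step from the
  grid edge, the shrinking fit range biases the argmax by about one step.

The 14-model family is a documented reconstruction (total magnitudes,
their interaction, and signed/absolute x–y component variants with x
taken toward the target); selection is by out-of-sample R² averaged
across units. Bootstrap R² intervals resample 50 ms blocks of fitted time
points within trial type and refit, respecting smoothing-induced
autocorrelation.

## Ideal observer

Per iteration: draw a class uniformly, hold out one trial of that class
per unit (units are pseudo-population, so trials pair only by resampling),
form class centroids from the remainder, classify by smallest Euclidean
distance, ties broken uniformly at random. A caution established during
development: the *conditional* chance accuracy on one fixed dataset has
dataset-level SD of several percent (the sample class-mean gaps are real
within a dataset), so chance behaviour is assessed by averaging over many
label-shuffled populations, not by one long run.

## Spectral analysis and PPC

Preprocessing: anti-aliased downsampling to 2 kHz (a warning notes
limited headroom below 4 kHz input), overlapping-window linear detrend
(1 s windows, triangular blending), mains sinusoid regression at 60 Hz
and harmonics, and automated artifact censoring at |robust z| > 6 with
±2.5 s exclusion. The "notch filter between 13 and 30 Hz" of the source
description is implemented as a band-*pass* — a notch would delete the
band being analyzed — combined with the Hilbert transform in one
frequency-domain step. All FFT work reflection-pads to fast lengths
(R's mixed-radix FFT degrades badly on awkward ones).

The Morse wavelet (γ = 3, time–bandwidth P² = 20, so β = 20/3) is applied
in the frequency domain over 30 log-spaced frequencies from 4 to 100 Hz
(the analysis floor of 4 Hz reflects the ~500 ms shortest windows), peak
normalized to 2 so a unit sinusoid at a centre frequency has
unit-magnitude coefficients. Evoked power is |complex trial mean|²;
induced is mean power minus evoked; both are normalized by
trial-count-matched baselines (100 resamples of n trials from the
pre-fixation −500…−250 ms epoch) because the expected evoked power of
zero-mean noise falls as 1/n.

PPC follows the pair-based estimator: per time–frequency bin (windows of
10 cycles capped at 1.5 s, ending at the time point, stepped 50 ms),
average cos(θᵢ−θⱼ) over spike pairs on *different* trials of the same
type, then over trial pairs, unweighted (a count-weighted variant is a
documented alternative; pair weighting is not specified beyond "averaged
over all pairs of trials"). The estimator is unbiased under independence
and estimates the squared population resultant; a sinusoidal rate
modulation of depth m gives resultant m/2, hence the conversion
m = 2√PPC and peak-to-trough modulation 2m/(1−m), which reproduces both
printed conversions (0.0042 → 30%, 0.0056 → 35%).

## Trajectory averaging

DTW uses the symmetric step pattern with Euclidean local cost and no
window, implemented in C++; pairwise means average aligned positions over
all ordered pairs including i = j (as in the identity the estimator is
derived from), resampled to 200 points equally spaced in warped time. The
pairwise variance N⁻³ Σₖ(Σₗ δₖₗ)² reduces exactly to the population
variance per time point for identity alignments — this, not a new
statistical claim, is what the oracle tests assert. Fréchet/Ward
clustering folds medial/lateral by |x| when shape, not side, is the
question.

## Known limitations

* The censored alpha-kernel PSTH is biased low within ~3/α of each
  censoring boundary; only the regression pipeline excludes the warm-up.
* Impromptu turn-onset detection has a heavier error tail (~100 ms at the
  90th percentile) than planned turns: the heading change during braking
  is gradual.
* The acceptance-grade one-grid-step lag recovery holds for strong
  movement units (baseline 80 Hz, R²≈0.7) in 135-trial sessions; at
  paper-median SNR the supported claim is ±20 ms.
* `cluster_units` cuts the tree at k = 3 by default (two main clusters
  plus remainder) because a coverage-maximizing rule is degenerate at
  k = 2; the cut is a reporting choice, not an inference.
* The pipeline analyzes one synthetic session; multi-session pooling
  beyond the mixed-effects contrast is out of scope.
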