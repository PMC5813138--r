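---
title: "Estimating BOLD magnitude and onset latency: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating BOLD magnitude and onset latency: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldlat)
```

## The model

Event-related BOLD responses are modelled per run as a linear
combination of stimulus-locked regressors.  Each event class (pooled
cues, each correct-target flanker condition, pooled error trials)
enters as a train of impulses convolved with two kernels:

* the **canonical HRF** — a double-gamma impulse response (response
  delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio
  1/6, 32 s support), rescaled to unit peak, peaking ~5 s after the
  event;
* its **temporal derivative** — the canonical kernel minus the same
  kernel delayed by 1 s, divided by the 1 s shift.

A response that starts slightly earlier or later than the canonical
shape loads linearly on the derivative, so the derivative-to-canonical
beta ratio carries onset-timing information.  The ratio is mapped to
seconds by the bounded sigmoid

$$\mathrm{latency} = \frac{2 \times 1.78}{1 + e^{3.1\,\beta_2/\beta_1}} - 1.78,$$

which is 0 at ratio 0, monotone decreasing, and saturates at ±1.78 s.
Positive ratios (response leading the canonical) map to negative
latencies.

### Derivative scaling: the pairing convention

The sigmoid's constants fix a scale for the derivative regressor.  For
a response delayed by a small $\delta$, least squares on the raw
shift-difference pair gives $\beta_2/\beta_1 \approx -\delta$, while
the sigmoid's slope at the origin is $-1.78 \times 3.1 / 2 \approx
-2.76$; applied to the raw ratio it would over-recover small shifts by
that factor.  The package therefore multiplies the derivative kernel by
$1.78 \times 3.1 / 2$, which makes the transform **first-order
unbiased**: small shifts are recovered exactly, by construction rather
than by numerical tuning.

Accuracy over the full range is limited by TR sampling and sigmoid
curvature.  In noiseless end-to-end simulations (TR 1.92 s, 156
volumes) the round-trip error is below ~0.03 s for |shift| ≤ 0.5 s and
grows to ~0.1–0.14 s at ±1 s; a dense scan over alternative kernel
scales shows no scaling does better than ~0.12 s maximum error on
[-1, 1], so this is a property of the transform itself, not of the
implementation.  The test suite asserts the measured profile (0.1 s in
the mid-range, 0.15 s at the edges) and, with noise at SNR 5, a mean
absolute error below 0.25 s with perfect rank ordering of seven true
shift levels.

### Stability masking

The ratio explodes when $\beta_1 \approx 0$.  Voxels enter a latency
map only when $|\beta_1 / \mathrm{se}(\beta_1)| \ge 1.65$ (a one-sided
p ≈ 0.05 cut; configurable).  Excluded voxels are `NA`, never 0, and
ROI latency means average the valid voxels only.  Deactivations
(negative $\beta_1$, as in the default-mode network) pass through the
ratio unchanged — the transform depends only on $\beta_2/\beta_1$ — so
latencies are defined for deactivating regions too.

## Design matrix and GLM

* Convolution is done on a 16x oversampled grid (dt = TR/16), then
  sampled at volume acquisition times; event onsets snap to the grid.
* Reaction-time parametric modulators (optional): per condition,
  impulses of height RT in seconds, mean-centred within condition
  within run, convolved with the canonical only.  Centring keeps the
  condition main effect interpretable; modulators are deliberately not
  orthogonalised against other conditions.
* Nuisance block: six rigid-body motion parameters, a discrete-cosine
  set with 128 s cutoff (`floor(2 * T / 128)` functions), and a
  constant.  The generator's drifts (periods 192 s and 288 s) lie
  inside the cutoff, and the suite verifies the canonical beta is
  biased by well under 2 % in their presence.
* Degenerate columns (a condition with no correct trials, a
  zero-variance modulator) are dropped and recorded; a run with no
  correct target at all is an error.  Remaining rank deficiency aborts.
* Each voxel is scaled to percent signal (divided by its temporal mean,
  times 100) so betas share units across subjects.  Zero-mean or
  zero-variance voxels are masked, not fatal.
* Serial correlation: one AR(1) coefficient per run, the lag-1
  autocorrelation of the OLS residuals averaged over in-mask voxels,
  then GLS by prewhitening of data and design.  Pooling follows the
  usual single-rho practice; the suite checks 95 % interval coverage of
  93–97 % across 1,000 AR(1)-noise voxels at rho = 0.3.  With rho fixed
  at 0 the GLS solution equals OLS to 1e-8 relative, which the suite
  asserts.
* Runs are combined within subject by the unweighted mean of betas
  (equal session weighting); degrees of freedom add.

## Quality control

Framewise displacement is the Euclidean norm of the frame-to-frame
differences of the three translations (mm) and, separately, the three
rotations (degrees).  Exclusion uses the peak absolute excursion of any
parameter from the run's first (reference) volume — the
alignment-target reading of a "3 mm or 3°" rule; both conventions are
reported side by side since printed summaries are typically framewise.
Exclusion triggers on >3 mm, >3°, or accuracy < 2/3, with reasons
recorded; no scrubbing or interpolation is ever applied.

Standardized DVARS divides the RMS volume-to-volume intensity change by
its expectation under temporally independent noise, estimated from
voxelwise robust SDs of the differenced series (IQR / 1.349).  White
noise scores 1.00 ± 0.05 at the suite's calibration size (150 volumes x
10,000 voxels); the statistic is scale-invariant, and a single
corrupted volume produces a localized spike above 3.

## Group statistics

The per-ROI analysis is a two-group x three-condition mixed
repeated-measures ANOVA implemented directly from sums of squares so
the error structure is explicit: the group effect is tested against
subjects-within-groups; condition and group x condition against the
condition-by-subject error, with Type III (unweighted marginal means)
conventions so unequal group sizes reproduce SPSS behaviour.
Greenhouse–Geisser epsilon comes from the pooled within-group
covariance of condition scores,
$\varepsilon = (\sum\lambda)^2 / ((k-1)\sum\lambda^2)$ over eigenvalues
of the double-centred covariance, bounded in $[1/(k-1), 1]$ and applied
to the within-subject tests only (the group effect has a 1-df
numerator).  Two independent oracles guard the implementation: a
hand-written spreadsheet-style decomposition and `car::Anova`'s
multivariate route, both agreeing to 1e-10 on random unbalanced
designs, plus a frozen 6-subject worked example.  Under a spherical
null the GG-corrected condition test holds its nominal 5 % size within
±2 % over 2,000 simulated datasets.

Secondary statistics: pooled-variance two-sample t from printed
summaries (df = n1 + n2 - 2), Bonferroni thresholds (alpha/m at 4
decimals; 0.05/9 = 0.0056), and Spearman correlations with average
ranks and the t-approximation p value.

## The synthetic cohort

The generator emulates a two-group attention-task study: 5-minute runs
at TR 1.92 s (156 volumes), six runs per subject, ~20–30 trials per run.

* **Reaction times** are lognormal, reparameterised to the configured
  arithmetic mean/SD per group and condition (positive, right-skewed).
  Defaults: control 714/1005/1084 ms (SD 121/217/265), patient
  1125/1521/1800 ms (SD 262/391/486) for congruent / easy- /
  hard-incongruent.  Accuracy defaults (0.97/0.93/0.90 control,
  0.92/0.87/0.82 patient) are a plausibility choice — high but
  difficulty- and group-graded, comfortably above the 2/3 exclusion
  floor — since only the exclusion rule, not an accuracy table, was
  available to pin them down.
* **Trial spacing**: inter-trial interval uniform 8–12 s after the
  response; cue-to-target interval uniform 0.5–1.5 s.  The cue jitter
  is essential, not cosmetic: with a fixed 1 s gap the cue regressor is
  almost exactly a linear combination of the target canonical and
  derivative columns (a 1 s shift is precisely what the
  shift-difference derivative encodes) and the design becomes
  near-singular.
* **Task-positive regions** respond with impulses at shifted onsets;
  default amplitudes and shifts are the configured group-by-condition
  region means.  Cues add a small fixed impulse (0.5 % signal).
* **Default-mode regions** respond with a negative boxcar lasting from
  the stimulus until that trial's response, at a constant per-group
  height (−2/−4 % for the posterior, −1/−2.5 % for the frontal
  component).  Deactivation magnitude therefore grows with reaction
  time by construction — condition and group differences in DMN
  magnitude emerge purely from RT, with no latency difference.  Note
  the fitted *latency* of a boxcar seen through an impulse basis sits
  mid-trial (positive), a semantic difference from the impulse regions.
* **Noise**: stationary AR(1) Gaussian per voxel (default SD 1 %
  signal, rho 0.3), two slow cosine drifts (periods 192 s and 288 s,
  random phases), baseline 100.  Background voxels carry the average
  noise character of the regions.  Motion is a smoothed random walk in
  six parameters, amplitude chosen to give framewise statistics of a
  few hundredths of a millimetre/degree.
* **Masks** are disjoint 3x3x3-voxel blocks on a 24x24x12 grid (3 mm
  isotropic) carrying the nine region labels; they are synthetic
  stand-ins, not anatomy.
* **Determinism**: every subject-by-run random stream derives from the
  cohort seed, so identical specifications give bit-identical event
  tables and voxel data.

What the generator does *not* emulate: anatomy and partial-volume
structure, physiological (cardiac/respiratory) noise, motion-induced
signal artifacts, and session-level nonstationarities.  Passing tests
therefore demonstrate correctness of the estimation machinery under the
stated forward model, not robustness to every property of real scanner
data.

## Numerical choices and problem sizes

Tolerances and sizes used by the suite, chosen to keep the full run in
tens of seconds on one CPU: GLS/OLS equality at 1e-8 relative; ANOVA
oracle agreement at 1e-10; type-I calibration over 2,000 simulated
datasets of 10 + 10 subjects; interval coverage over 1,000 voxels;
DVARS calibration at 150 x 10,000; latency recovery on single-region
8x8x4 grids; power checks over 150 summary-level cohorts at the 23 + 32
group sizes with a 0.3 s injected latency effect (between-subject SD
0.2 s, residual SD 0.15 s, in the range of typical regional latency
SDs).  The acceptance script simulates behavioural cohorts with 20 runs
per subject so every condition has at least ~100 correct trials.

## Known limitations

* Latency recovery degrades near ±1 s true shift (~0.1–0.14 s error)
  and saturates beyond ±1.78 s by construction; shifts outside the open
  interval are unrepresentable and the generator refuses them.
* The pooled AR(1) estimate from OLS residuals is biased slightly
  toward zero (projection onto a ~20-column design); coverage remains
  within the asserted 93–97 % band, but rho itself should not be read
  as an unbiased noise parameter.
* The cue and target regressors remain correlated at short
  cue-to-target intervals even with jitter; single-run condition betas
  are noisy and stabilise through run combination.
* `rm_anova` requires complete cases and drops subjects listwise, in
  keeping with the balanced repeated-measures formulation.
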