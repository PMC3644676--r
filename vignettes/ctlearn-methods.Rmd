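---
title: "Methods: continuous-tracking sequence learning, from stimulus to group map"
author: "ctlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous-tracking sequence learning, from stimulus to group map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctlearn` implements the analysis chain of an implicit motor
sequence-learning study built on the continuous tracking (CT) task:
participants follow a vertically moving target with wrist movements on a
joystick, and a fixed ("repeated") trajectory segment is covertly embedded
among freshly generated ("random") segments. Superior tracking of the
repeated segment at a delayed retention test indexes sequence-specific
learning. The package covers stimulus synthesis, kinematic scoring,
behavioral summary statistics, the block-design fMRI GLM, and the
behaviorally weighted group correlation image, together with a fully seeded
synthetic cohort used to validate the whole chain against known ground
truth.

## Stimulus model

Each 10-s target segment is one period of a sixth-order sinusoidal series

$$f(x) = b_0 + \sum_{k=1}^{6} a_k \sin(kx) + b_k \cos(kx),
\qquad x \in [0, 2\pi],$$

rendered at the 50 Hz joystick sampling rate (500 samples; the endpoints
coincide by periodicity). A 20-s trial links one repeated and one random
segment, with the order counterbalanced so that exactly half the trials in
every 10-trial block present the repeated segment first.

Random segments draw `a1..a6`, `b1..b6` independently and uniformly from
[-10, 10]. Each candidate is then:

1. **centred** — shifted by $(\max f + \min f)/2$ so its extremes are
   equidistant from the screen midline (this plays the role of choosing
   $b_0$);
2. **endpoint-zeroed** — a linear ramp between the two endpoint values is
   subtracted so both ends land exactly on 0, where consecutive segments
   are linked on screen. For a periodic render the ramp is numerically a
   constant, so the interior shape, range of motion and velocity profile
   are unchanged.

These two constraints cannot both hold exactly for a generic shape: after
the ramp the midline symmetry is off by the (usually small) endpoint value.
We let the endpoint constraint win, because the display links segments at
zero crossings; the applied midline offset is kept in `$midline_offset` for
inspection.

Candidates whose excursion leaves the ±20° display range are rejected
outright (an alternative would be rescaling; rejection keeps the
coefficient distribution honest). Survivors face three difficulty-equating
screens against the repeated segment:

* range of motion within **5%** of the repeated segment's;
* mean absolute velocity at least `velocity_floor_frac` (default **0.8**)
  of the repeated segment's — the original floor was derived empirically
  from pilot rankings and is not recoverable, so the fraction is exposed as
  a parameter;
* junction slope within **20%** of the repeated segment's slope, at *both*
  link orderings (random-then-repeated and repeated-then-random), so an
  accepted segment can occupy either position in a counterbalanced trial.

The joint acceptance rate of the display limit plus screens is on the order
of $10^{-4}$, so `sample_random_segments()` evaluates candidates in
vectorized batches drawn from a single seeded stream, with an exact
pre-reject (range of motion measured on a subgrid is a lower bound on the
true range, so a subgrid range above the admissible cap proves rejection).
First-passing-candidate semantics are preserved, so results are identical
to the one-at-a-time loop.

**Repeated-segment coefficients.** The original stimulus coefficients are
not recoverable, so `default_repeated_coefficients()` ships a synthetic
stand-in: a coefficient vector drawn once from the same uniform family and
frozen, selected to be *typical of the screened pool* (range of motion
≈ 34.8°, maximum excursion 17.6°, mean |velocity| ≈ 14°/s, junction slope
≈ 32°/s in magnitude). Placing the reference near the pool's mode is also
what makes the 5% range-of-motion screen satisfiable at a practical rate.

## Kinematic decomposition

For each tracked segment, three measures are computed from the paired
target/response streams:

* **Overall error** — RMSE between response and target angles (degrees).
* **Temporal precision** — the time lag at which the target–response
  cross-correlation peaks. For every integer shift in ±2 s (the window is
  our choice; it comfortably contains plausible tracking lags) the Pearson
  correlation is computed over *only the continuously overlapping samples*,
  re-centred per shift, with no padding — avoiding the sample-size biases
  that padding introduces. The shift maximizing the squared correlation is
  the lag, reported in milliseconds, negative when the response trails the
  target. Exact ties break toward the smallest absolute shift (favouring
  the null of no lag). Lags are integer-sample (20 ms at 50 Hz); we do not
  interpolate below one sample.
* **Spatial accuracy** — the squared correlation $R^2$ at the best lag, and
  the *spatial error*: RMSE recomputed after shifting out the lag, again
  over the overlap only.

The per-shift correlations are computed either by an explicit loop
(`method = "direct"`) or via one FFT cross-correlation plus cumulative-sum
bookkeeping (`method = "fft"`, the default); the two agree to round-off and
the direct loop serves as the oracle in the test suite. A lag estimate is
flagged unreliable when the peak correlation magnitude falls below
`min_peak_r` (default 0.2), and degenerate when no shift has a defined
correlation (zero variance everywhere, e.g. a constant target).

## Behavioral summary

Per subject, day and measure, the **difference score** is the mean over
repeated segments minus the mean over random segments. The statistical
weight inverts the sign for the two error measures (RMSE, spatial error) so
that a positive weight always denotes a sequence-specific advantage; the
lag difference keeps its sign (lag nearer zero on repeated segments is an
advantage). `count_positive()` counts strictly positive weights. The
bundled `weighted_scores_table()` reference cohort (n = 10) reproduces the
sign counts 3 (overall error), 8 (temporal precision) and 1 (spatial
accuracy).

Outliers are removed in a single pass: values more than 2 SD from the group
mean, with mean and SD computed once on the full table and an exclusive
boundary. The day-by-sequence repeated-measures ANOVA is the standard
balanced two-way within-subject decomposition (each effect against its own
subject-by-effect stratum), fitted via `stats::aov()` with an
`Error(subject/(day*sequence))` term and verified in the tests against a
hand-written sums-of-squares oracle; a Mauchly sphericity statistic for the
day factor is attached when estimable, but no sphericity corrections are
applied. Zero-variance effects report F = 0; zero error variance with a
non-zero effect reports F = ∞ with a degenerate flag rather than NaN.

Explicit recognition uses the forced-choice criterion: at least 2 of 3 true
sequences recognized *and* at least 4 of 7 foils rejected.

## First-level fMRI model

Each scan day comprises four 7-min runs in the fixed block design 40 s
rest / 150 s stimulation / 40 s rest / 150 s stimulation / 40 s rest
(420 s, 210 volumes at TR 2.0 s). Each stimulation block carries a single
sequence condition and the condition order alternates across runs. The runs
of a day are concatenated and fitted jointly with ordinary least squares.
The design matrix holds:

* two condition boxcars convolved with a canonical double-gamma HRF
  (response gamma shape 6, undershoot shape 16, ratio 1/6, unit peak;
  convolution on a 0.1 s grid, then sampled at volume times);
* the six motion parameters, taken as given (head-motion realignment is out
  of scope);
* a per-run baseline and linear drift — a necessity of concatenation.

That is $2 + 6 + 2R$ columns for $R$ runs. Rank-deficient designs are
rejected with the aliased columns named. The Repeated−Random contrast is a
t image by default (suited to the weighted group analysis below, where
unit-scale per-subject images make the null calibration meaningful); a raw
amplitude-difference mode exists for noiseless analyses. Voxels with
residual variance indistinguishable from zero (relative to the voxel's
total variance) are capped at the largest finite |t| and flagged rather
than propagating infinities.

Spatial smoothing is a separable 3D Gaussian with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis, kernels truncated at
$4\sigma$ and renormalized so constants (and image edges) are preserved;
the default FWHM is 4 mm at 4 mm isotropic voxels, applied before fitting.

## Behaviorally weighted group image

Given per-subject contrast images $c_i(v)$ and weights $w_i$, the group
statistic is

$$g(v) = \frac{1}{\sqrt{N}} \sum_{i=1}^{N} w_i\, c_i(v).$$

Two optional weight transforms are exposed:

* **mean-centring** (default off, matching the literal procedure). With raw
  all-positive weights, a region activated *uniformly* across subjects
  — with no behavioral coupling at all — still sums to a large positive
  statistic. Mean-centring removes exactly this confound (for identical
  images the centred sum is identically zero); the simulator includes a
  uniform-activation region so the behavior is demonstrable either way.
* **RMS scaling** (divide by the root-mean-square weight; the pipeline
  default). The statistic is thresholded against a standard-normal null,
  which is only plausible if the weight vector has unit scale when the
  $c_i$ are unit-scale t images; raw weights in milliseconds would inflate
  the null by orders of magnitude. The bundled reference cohort's weighted
  scores are of order one, consistent with some such normalization having
  been applied.

Thresholding converts the statistic to a one-sided p-value in the positive
tail of a standard normal, keeps voxels with $p$ below the threshold
(0.005 for the overall-error analysis; 0.0005 for the temporal and spatial
component analyses), labels connected components — face connectivity (6) by
default, 18/26 available, since "contiguous" is otherwise ambiguous — and
discards clusters below 200 voxels. Peaks are reported as 0-based grid
indices and mm offsets; no atlas registration is attempted. Finally,
`day_overlap()` implements the interpretation rule: voxels suprathreshold
on both day 1 and day 7 are performance-related; the learning-specific set
is the day-7 set minus that overlap.

## The synthetic cohort and what it can show

The simulator generates the *study conditions*: 10 subjects; practice days
2–6 with 50 trials/day (5 blocks of 10); scan days 1 and 7 with four
210-volume runs. Behavior follows a lag-learning model: subject $s$ tracks
with lag $L_s \, e^{-r_{s,k}(d-1)}$ ms on day $d$ for sequence kind $k$,
with baseline $L_s \sim \mathcal{N}(-300, 30^2)$ ms and decay rates
$\mathcal{N}(0.4, 0.08^2)$/day for repeated versus
$\mathcal{N}(0.1, 0.04^2)$/day for random tracking (truncated at zero), so
by retention the lag difference score is positive for essentially every
subject with magnitude ≈ 100–200 ms. Responses are the target delayed by
the programmed lag plus 1° Gaussian motor noise — roughly 10% of a typical
segment's amplitude SD.

BOLD runs live on a 20×20×20 grid (4 mm voxels; no anatomical realism)
with baseline 1000, task amplitude 10 (a 1% signal change), white noise
SD 15, per-run linear drifts, and smooth motion series leaked into the
signal (removable exactly by the motion regressors). Three disjoint
rectangular regions define the ground truth: a *behavior-coupled* block
whose Repeated−Random amplitude is `coupling_gain` (0.05 signal units per
ms) times the subject's measured lag weight; a *uniform* block with the
same fixed contrast in every subject (probing the mean-centring confound);
and a *null* block equally active in both conditions. The simulation HRF is
the same canonical double-gamma as the GLM — deliberately, so that recovery
failures indicate pipeline defects rather than model mismatch; HRF
parameters can be perturbed for robustness experiments.

`recovery_study()` runs the full chain for one simulated experiment — scan
day behavior (15 segments per condition per day, one run's worth), lag
weights from the kinematics and summary modules, BOLD simulation coupled to
those same measured weights, GLM, weighted group image (RMS-scaled weights,
p < 0.0005, 200-voxel extent) — and reports the fraction of coupled-region
voxels recovered and the false-positive fraction in the null region. The
stimulus battery is generated once from its own seed and reused across
experiment seeds, as a real lab would reuse one stimulus set across
experiments. The acceptance suite aggregates 20 such experiments.

Passing these checks shows the chain is *internally consistent* — signals
generated under the model are recovered at the stated thresholds. It does
not certify performance on real data, where the HRF varies, noise is
temporally autocorrelated and physiological, motion corrupts more than it
leaks, and anatomy matters; none of those are modelled.

## Numerical choices and problem sizes

* Lag search ±2 s; integer-sample lags; ties to the smallest |shift|;
  unreliable below peak |r| = 0.2.
* Zero-variance detection in the correlation bookkeeping uses a relative
  tolerance ($10^{-12}$ of the accumulated sum of squares).
* Segment sampling batches 5000 candidates; the attempt cap (default
  3×10⁶) exists to turn pathological configurations into an informative
  error listing per-screen rejection counts.
* The ANOVA requires exactly one value per cell (aggregate first);
  incomplete designs are rejected rather than imputed.
* Test and validation sizes were chosen to exercise the full study design
  at desk scale: the recovery study uses the complete 4-run, 2-day,
  10-subject layout on the 20³ grid over 20 seeds; unit tests use smaller
  grids (8³–12³) and shorter schedules.

## Known limitations

* The repeated-segment coefficients are a documented synthetic stand-in;
  the bundled reference
  cohort's per-participant weighted-score *magnitudes* are on an unstated
  normalized scale and are not reproduced — only their signs.
* No prewhitening or autocorrelation modelling in the GLM; inference on
  real BOLD data would be optimistic.
* No registration, atlas labeling, or multiple-comparison machinery beyond
  the stated threshold-plus-extent rule.
* The cluster-extent value (200 voxels) is taken as given and exposed as a
  parameter; no simulation-based calibration is performed.
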