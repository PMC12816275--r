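---
title: "Oculomotor feature analysis for free-viewing screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oculomotor feature analysis for free-viewing screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`oculoscreen` turns raw screen-based gaze recordings — one row per sample
with timestamp, pixel position and a validity flag, nominally at 90 Hz on a
1920x1080 display viewed at 70 cm — into an oculomotor screening analysis:
cleaning, event segmentation, eleven per-trial features in three families,
scanpath-similarity and reliability summaries, two-group statistics, and
leave-one-out cross-validated classification. Because clinical gaze
recordings are rarely shareable, the package also contains a synthetic
two-cohort generator whose defaults emulate the statistical structure of a
free-viewing face-exploration experiment contrasting a neurologically
impaired group with healthy controls. This vignette documents the models,
the tunable parameters, the numerical choices, and what the test suite
does and does not establish.

## Geometry

All velocity and amplitude features are expressed in degrees of visual
angle. Pixels are treated as square; the pixel pitch is derived from the
display diagonal and the resolution, and a displacement of $d$ pixels
subtends $\theta = \arctan(d \cdot \mathrm{pitch} / D)$ degrees at viewing
distance $D$. At the default geometry one degree is about 44.5 px. A
pixel-unit mode (`trial_features(units = "px")`) is provided because
published magnitudes for these features are sometimes printed in degree
units that are physically implausible for saccades (e.g. three-digit
"degree" amplitudes on a screen that subtends roughly 41 degrees); such
values are only consistent with pixel units, so the package exposes both
and leaves the unit system to the analyst.

## Preprocessing

Cleaning follows a fixed order: blink classification, then gap
interpolation, then trial-level quality control. The order matters — a
blink must never be "filled in" by interpolation, which is only consistent
if blinks are classified before interpolation runs.

* **Blinks**: validity-0 runs lasting 75–500 ms, plus a one-sample margin
  on each side, are marked removed. The window is a heuristic (recordings
  do not label blinks); both bounds and the margin are configurable.
* **Gaps**: any remaining invalid run strictly shorter than 75 ms that is
  flanked by valid samples is filled by linear interpolation of x and y.
  Gap duration is measured between the flanking valid samples minus one
  inter-sample interval, which is robust to timestamp jitter.
* **QC**: a trial is dropped when its missing fraction (invalid or removed
  samples relative to the expected count at the nominal rate) strictly
  exceeds 20%. Exactly 20% is kept.

Interpolation is idempotent and never alters timestamps or sample counts.

## Event segmentation

Fixations and saccades are segmented with a velocity-threshold detector
(I-VT): point-to-point angular velocities by central differences,
sub-threshold runs become fixation candidates, candidates shorter than the
minimum duration are discarded, and the intervals between retained
fixations become saccades. The defaults — 30 deg/s threshold, 60 ms
minimum fixation, no additional smoothing — are conventional for trackers
near 90 Hz, where heavier filtering distorts more than it helps. A
dispersion-based detector (I-DT) is available as an alternative.

Three details matter at low sampling rates:

* **Merging**: adjacent retained fixations closer than 0.7 deg and
  separated by less than 75 ms are merged, which suppresses splits caused
  by single noisy velocity samples.
* **Boundary reattachment**: a sample flanking a retained run has a
  velocity estimate contaminated by the neighbouring saccade (the central
  difference spans the ramp) even when its position still lies on the
  fixation. Samples within 0.05 deg of the run centroid are reclaimed, so
  fixation durations are recovered to within one sample interval on
  noise-free schedules.
* **Saccade metrics**: amplitude is the vectorial distance between the
  flanking fixation centroids (noise-robust; the path-integrated quantity
  lives in the scanpath-length feature), mean velocity is amplitude over
  the inter-fixation interval, and peak velocity is the maximum sampled
  point velocity across that interval including its boundary samples. At
  90 Hz a typical saccade spans only 2–4 samples, so the sampled peak can
  fall below the gap-based mean; the package reports both definitions
  exactly rather than clamping one to the other, and the inequality
  "peak ≥ mean" should be read as holding only up to sampling effects.

Events never span a removed (blink) or lost stretch of samples.

## The eleven features

Saccadic family: mean vectorial saccade velocity (deg/s), mean vectorial
amplitude (deg), inflection count (sign changes of the horizontal plus
vertical displacement components across consecutive saccades, with a 1 px
jitter floor under which a component inherits the previous sign), mean
peak velocity (deg/s), and the velocity waveform indicator — the OLS slope
of per-saccade mean velocity on peak velocity. The regression orientation
is configurable because group summaries of this statistic are only below
one for the mean-on-peak orientation; trials whose peak velocities vary by
less than 1% of their level return `NA` (the slope is then noise-dominated).

Fixation family: mean fixation duration (ms), fixation count, and regions
of interest — single-linkage clusters of fixation centroids at a 2 deg
radius containing at least two fixations. This is a data-driven feature
and deliberately distinct from the fixed reliability AOI rectangle.

Scanpath family: Shannon entropy of gaze dispersion over an 8x8 grid of
equal screen cells ($H = -\sum_i p_i \log_2 p_i$ over occupied cells,
where $p_i$ is the fraction of fixations in cell $i$), scanpath length
(summed vectorial distances between consecutive centroids, deg), and
scanpath area (convex hull of the centroids, deg²). The 8x8 grid is coarse
enough that ~25–30 fixations per trial give stable occupancy estimates.

Undefined features (no saccades, no fixations, degenerate regression) are
reported as `NA`, never as zero.

## Scanpath similarity

Two scanpaths are compared by global sequence alignment over their
fixation sequences. Substituting fixation $i$ for fixation $j$ costs

$$ s_{ij}\,|d_i - d_j| + (1 - s_{ij})\,(d_i + d_j), \qquad
   s_{ij} = m^{\,\Delta_{ij}} $$

with $d$ the durations (ms), $\Delta_{ij}$ the spatial separation in
degrees and $m = 0.83$ the per-degree modulation; inserting or deleting a
fixation costs its duration. Perfectly co-located fixations therefore cost
their duration difference, far-apart fixations their combined duration.
The minimal alignment cost is found by dynamic programming and verified in
the tests against exhaustive enumeration of all alignments for short
paths. Similarity is the order-reversing map $s = 1 - c/(T_a + T_b)$,
where $c$ is the cost and $T$ the total durations, so identical paths
score 1. Absolute similarity levels depend on this normalization choice;
only orderings (within-subject versus between-subject similarity) are
treated as meaningful, and the tests assert the ordering, not levels.

Intra-individual similarity averages all trial pairs within a subject;
inter-individual similarity averages all subject pairs within a group on
the same stimulus, then averages over stimuli.

## Reliability

Two data-quality surfaces: the proportion of fixations (and of fixation
time) inside a fixed 600x450 px rectangle centred on the stimulus, with
boundary centroids counted inside; and intraclass correlations of each
feature over the first 3, 5 and 7 retained trials per subject. The default
ICC form is ICC(3,k) — two-way mixed, consistency, average measures —
because the statistic is used as internal consistency of a fixed trial
set; ICC(3,1), ICC(2,1) and ICC(2,k) are available. The mean squares come
from the closed-form balanced two-way decomposition, verified against
`aov()` in the tests. Subjects lacking a subset's trial count are excluded
from that subset; fully degenerate matrices report 1 with a flag.

## Group statistics

Each feature is compared between groups through a Shapiro–Wilk gate at
$\alpha = 0.05$ per group: both compatible with normality leads to a
pooled-variance two-sample t-test with Cohen's d, otherwise a Mann–Whitney
U test with the rank-biserial correlation $r = 1 - 2U/(n_a n_b)$. All p
values are two-tailed; effect-size confidence intervals use a seeded
percentile bootstrap. No multiple-testing correction is applied by
default (a Holm option can be applied downstream by the analyst).

The unit of analysis deserves care. Trials are nested in subjects, so
treating trials as independent observations is anti-conservative for any
between-subject variability (pseudoreplication); the package's default is
therefore subject-level (per-subject trial means), with the trial-level
mode available for comparison with analyses that report trial-scale
degrees of freedom. The direction-recovery property test in the acceptance
suite runs at subject level on a 100+100-subject simulated cohort: at that
size every injected effect is detectable at a valid unit of analysis,
whereas at a small clinical n the weakest effects (scanpath area, region
count) would be confounded with power, and at trial level the
gaze-dispersion entropy null could not be tested honestly.

## Classification

Per-trial features are arranged subject-wise into a wide matrix with one
column per (feature, trial) pair, which keeps each subject on one side of
every cross-validation split; subjects with missing trials are imputed
with their own per-feature median. Feature selection is L1-regularized
logistic regression with the penalty located by bisection so that exactly
k = 10 columns survive (plateaus fall back to the nearest achievable count
below k; a degenerate fit falls back to a univariate correlation screen so
downstream models always receive a non-empty design).

Evaluation is leave-one-out: scaling, selection and the classifier are
re-fit on the n−1 training subjects of every fold. Four classifier
families are provided — an RBF-kernel support vector machine, extremely
randomized trees, and two gradient-boosted tree variants (a standard tree
booster and a DART booster with dropout), all with fixed shallow-tree
hyperparameters (depth ≤ 3, ≤ 120 rounds, seeded) and no per-fold tuning.
Accuracy and F1 (positive class = impaired) come from pooled hard
predictions at a 0.5 probability threshold. For the threshold-free curve
metrics (AUROC, AUCPR) the pooled scores are first centred by each fold's
mean training score: naive pooling is systematically anti-ordered under
the null because each fold's training class balance shifts its score
scale. Label-permutation checks of the pooled AUROC are run on a
no-effect cohort; when the feature matrix itself contains a two-cluster
partition, scores correlate with the cluster's permuted label majority
and the permutation distribution is no longer centred at one half, so a
structured cohort is not a valid permutation null for this statistic.

The global (selection once on all subjects) variant is available via
`loocv_evaluate(select = "global")` for comparison only; it leaks the
held-out subject into selection and is not the default.

## The synthetic cohort generator

The generator is the package's stand-in for a clinical free-viewing
experiment: two groups (default 20/20 subjects; the study shape is 23
controls and 16 impaired), 10 stimuli x 10 s at 90 Hz, blink artifacts at
0.15/s with 100–300 ms duration, and 2% random sample loss — values taken
from the experimental protocol the package emulates where that protocol
states them.

Each trial draws its fixation targets i.i.d. from a subject-weighted
distribution over a face-like anchor layout (eyes, brows, nose, mouth,
chin, forehead plus peripheral points), then orders the drawn multiset by
a greedy locality tour in which the next target is chosen among the
remaining draws with probability decaying over distance. This
draw-then-order construction is the generator's central design decision:
the spatial occupancy distribution — and with it the gaze-dispersion
entropy — is identical in law across groups, while the sequencing (and so
saccade amplitude and scanpath length) is not. Fixation durations are
log-normal (strictly positive, right-skewed, as oculomotor durations are);
saccades follow a main-sequence duration–amplitude rule with a symmetric
beta-family velocity profile whose exponent controls the peak-to-mean
velocity ratio. Subjects carry multiplicative log-normal random effects on
duration, locality and saccade speed, idiosyncratic anchor offsets, and a
whole-layout translation; stimuli perturb the shared layout slightly. The
subject components dominate the stimulus components, which is what makes
a subject's scanpaths on different stimuli more alike than two subjects'
scanpaths on the same stimulus.

The impaired group receives multiplicative effects, with defaults set once
from the ratios of the printed group means of the clinical comparison the
generator emulates: fixation duration x1.08, saccade rate x0.97 (both act
before detection-level merging, which inflates the measured duration ratio
to ≈1.13–1.16), saccade amplitude x0.86 (applied with a quadratic response
on the locality scale so the measured mean amplitude moves roughly
one-to-one), saccade speed x0.80, exploration extent 0.65 applied as
compression of eccentricity beyond a 260 px knee about the layout centroid
(the periphery that defines the scanpath hull contracts while the central
mass that drives grid entropy stays put), a flattened velocity profile
(shape factor 0.37, raising the mean-to-peak ratio and with it the
velocity waveform indicator), a x2.5 amplification of the whole-layout
translation (lesion heterogeneity: impaired subjects' exploration patterns
diverge more from each other, lowering inter-individual similarity without
widening any one subject's coverage), and a x1.30 fixation landing scatter
(impaired targeting accuracy), the last value chosen so that the residual
entropy difference from the peripheral compression is cancelled and the
net injected entropy effect is null — the emulated comparison reports no
entropy difference, and the generator is required to reproduce that null.
These couplings were calibrated on dedicated diagnostic cohorts and then
frozen; they are properties of the generator's defaults, not per-analysis
dials.

What the generator does **not** emulate: pupil dynamics, smooth pursuit
(the emulated stimuli are static), vendor-specific noise spectra or drift,
stimulus-content-driven salience (every "face" shares one anchor
template), and the strong central concentration of real face viewing —
the synthetic layouts put only about half of the fixation mass inside the
standardized 600x450 AOI, versus the high proportions typical of real
faces. Passing tests therefore establish that the pipeline recovers known
structure from data with realistic sampling, artifact and nesting
properties; they do not certify performance on any real cohort, and the
near-ceiling synthetic classification metrics should not be compared with
clinical accuracy figures.

## Numerical choices and degenerate inputs

* Reproducibility: every stochastic routine takes a seed and restores the
  caller's RNG state; identical spec and seed give bit-identical cohorts,
  selections and model grids (for the deterministic model families).
* Zero-variance comparisons are flagged and skipped, not tested.
* ICC values are clipped below at −1; fully constant matrices report 1
  with a degenerate flag.
* Empty scanpaths are an error for the dissimilarity; single-trial
  subjects report `NA` intra-individual similarity.
* Trials with fewer than two usable samples yield empty event sets with a
  warning.
* Problem sizes in the shipped tests: oracle suites run on 60–100 small
  randomized instances; calibration checks use 2000 replicates; the
  direction-recovery cohort is 100+100 subjects x 6 trials; the
  permutation null uses 200 permutations of a 39-subject cohort; the
  multi-type comparison averages 20 replicate 13+13-subject cohorts.

## Known limitations

Boundary reattachment and fixation merging slightly bias measured
durations upward relative to the generating schedule on noisy data (the
bias is group-fair and cancels in comparisons). The exactly-k selection
can be unattainable on plateaus of the regularization path, in which case
the nearest achievable count is used and flagged. Pooled LOOCV curve
metrics remain mildly pessimistic at very small n even after per-fold
centring. The AOI rectangle is centred per stimulus via configuration; no
stimulus-specific landmark AOIs are provided.
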