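---
title: "Motor connectivity biomarkers by multiple kernel learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor connectivity biomarkers by multiple kernel learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mklconn)
```

mklconn implements a systems-level resting-state fMRI analysis for two-group
(patient versus control) studies of motor network disease: seed-based motor
connectivity features classified by a multiple-kernel-learning (MKL) support
vector machine with per-region kernels, plus a complex-network
characterization of the parcellated connectivity graphs. Because no scan
data ships with the package, a synthetic cohort generator provides study
conditions in which every stage — and the direction of every group effect —
is known by construction. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
conditions do and do not establish about real data.

## The synthetic cohort

Region-level BOLD-like series are stationary Gaussian AR(1) processes whose
*spatial* covariance is a block-structured correlation matrix: unit
diagonal, `base_coupling` (default 0.35) within blocks, `base_coupling / 2`
between blocks. The blocks are a cortical motor block (M1, SMA, paracentral
lobule), a subcortical motor block (basal ganglia, thalamus, cerebellar
subdivisions), and non-motor blocks of 4 regions. Patients differ from
controls by three planted effects:

* `delta1` — *increase* of coupling within the subcortical motor block
  (hyper-connected subcortical motor networks),
* `delta2` — *decrease* of subcortical-to-cortical motor coupling,
* `delta3` — *decrease* of motor-to-non-motor coupling.

The AR(1) smoothing (`ar_coef = 0.3`, innovations scaled by
`sqrt(1 - ar_coef^2)`) is applied after drawing spatially correlated
innovations, so the target covariance is the stationary spatial covariance
and the planted effect sizes remain interpretable as correlation
differences. Both group matrices are checked for positive definiteness at
construction; a near-singular matrix is ridge-repaired with a logged
`(Sigma + rI)/(1 + r)` shrinkage and rejected if `r` would exceed 10%.

Voxel series replicate their region signal plus independent Gaussian noise
(`voxel_noise_sd`, default 0.5 relative to the unit-variance signal). Six
motion parameters (smoothed random walks), a CSF and a WM series (smoothed
noise) are injected *additively with per-region random loadings* into region
and voxel series — voxels inherit their region's loading — so nuisance
regression is a meaningful operation rather than a no-op. Default
amplitudes (0.8 at full scale, 0.5 in the desk presets) put the nuisance
power on the order of the signal power, which is the regime reported for
resting BOLD confounds.

No quantitative effect sizes for the connectivity differences are available
from the study this emulates — only their directions — so the deltas are
free parameters. They are fixed once in the presets
(`desk_cohort_spec()`): the strong "classification" preset uses
(0.30, 0.25, 0.25), the "network" preset (0.30, 0.15, 0.10), and the "null"
preset (0, 0, 0). The network preset uses milder decoupling because with
`base_coupling/2 = 0.175` a `delta2` at 0.25 or above drives
subcortical-to-cortical correlations negative; after pruning this isolates
the cortical motor nodes entirely, which is a stronger lesion than the
reported "reduced coupling" and makes path length undefined for those
nodes. The parameter-recovery tests are the only calibration target of
these values, as the conditions themselves prescribe.

**What the generator does not emulate:** hemodynamic response shapes,
spatial autocorrelation within regions beyond common signal, motion spike
artifacts, scanner drift beyond a linear trend, registration error, or
anatomical geometry (the "atlas" is a lookup table, not a volume). Passing
tests therefore demonstrate that the implementation recovers planted
covariance structure through the full pipeline — not that the pipeline would
attain any particular accuracy on scanner data.

## Preprocessing

The stage order is fixed: (1) ordinary least squares regression of 16
nuisance series (6 motion + CSF + WM and their first derivatives) out of
every series, with an intercept always included; (2) per-series linear
detrending; (3) band-pass to 0.03–0.06 Hz with an order-4 Butterworth
filter. Choices the procedure leaves open, decided here:

* Derivatives are backward first differences with the first sample
  replicated (preserves length `T`).
* Filtering is zero-phase (forward–backward), selectable to single-pass by
  `zero_phase = FALSE`. Zero-phase doubles the effective attenuation
  order; `bandpass_response()` exposes the analytic two-pass magnitude so
  tests compare the implementation against it rather than against nominal
  single-pass attenuation.
* Edge handling: reflect padding of three filter orders at each end,
  trimmed after filtering.
* Rank-deficient nuisance designs drop collinear columns with a logged
  warning (this happens by construction when a noiseless cohort is
  generated with zero motion amplitude).

## Features: seed maps and per-ROI PCA

Each seed (default: one per motor region except the paracentral lobule —
12 per hemisphere: M1, SMA, caudate, putamen, pallidum, thalamus and six
cerebellar subdivisions, 24 in all) contributes one correlation map per
subject: Pearson correlation of the seed's mean course with every voxel.
Zero-variance voxels get correlation 0 with a logged count.

Maps are reduced by anatomical ROI with across-subject PCA: each
(seed, ROI) block of subjects-by-voxels values is centered per voxel and
projected onto its top-`k` principal directions; `k` scores are kept per
block regardless of ROI size (k = 10 at full scale, giving
116 × 24 × 10 = 27,840 features; k = 3 in the desk presets where regions
have 4 voxels). Blocks with fewer directions than `k` are zero-padded with
a log note. The sign convention makes each direction's largest-magnitude
loading positive, so results are reproducible across platforms. Centering
is per voxel (the standard choice for across-subject PCA); per-subject
centering would instead remove each subject's map mean.

Two PCA provenance modes exist. `"cohort"` (the default, matching the
reference procedure) fits the PCA across *all* subjects before
cross-validation, which leaks held-out information into the features; a
message notes this at fit time. `"fold_safe"` refits the projections inside
every outer training set and applies them to the held-out subject. Both are
tested; the leakage of `"cohort"` mode is demonstrated in the test suite by
perturbing a held-out subject and observing training-subject features move.

## The MKL classifier

Within each outer training set, features are z-scaled (mean/sd with the
n−1 convention; test rows scaled by training statistics), ANOVA-filtered to
the top 10% of columns per ROI (one-way F statistic, ceiling rule so no ROI
empties, ties to the lower column index), and each subject's vector is
normalized to unit length. Each ROI then contributes an RBF kernel
`exp(-gamma ||x_i - x_j||^2)` over its surviving columns.

The MKL model combines kernels with nonnegative weights `d` on the
probability simplex. The exact block-diagonal weight optimization used by
the original software is not described in the available text; the package
uses a standard alternating surrogate with the same interface:

1. for fixed `d`, solve the soft-margin SVM dual on `K = sum_m d_m K_m`
   (an SMO solver with second-order working-set selection, written in C++;
   its solutions are verified in the tests against an independent QP
   solver and kernlab's SMO to 1e-6);
2. update `d_m <- d_m * sqrt(S_m)` and renormalize, where
   `S_m = d_m * (alpha y)' K_m (alpha y)` is kernel `m`'s contribution to
   the squared weight norm (`sum_m S_m = ||w||^2`);
3. iterate until `max |delta d| < 1e-4` or 100 iterations.

A damped step halves the update toward the previous weights whenever the
fixed-`d` dual value would increase, so the recorded objective path is
non-increasing by construction; if damping fails eight times the current
iterate is returned. A `uniform` weight mode (fixed equal weights) is
available for ablation. With one kernel the model reduces exactly to a
standard RBF SVM. Warm starts (previous `alpha` re-used across weight
updates, ROI counts and elimination rounds) accelerate the solver without
changing solutions, since each solve runs to the same KKT tolerance.

Recursive kernel elimination repeatedly fits the model and removes the
kernel with the smallest `S_m` (ties: the higher ROI index leaves first);
the ranking is the reverse elimination order.

### Two-tiered leave-one-out

The outer LOO holds out one subject at a time. All transform statistics
(scaling, F statistics, rankings, and in `fold_safe` mode the PCA) come
from the outer training set only. The ROI ranking is computed once per
outer training set at reference hyperparameters (the median of each grid) —
recomputing it per inner fold is the stricter alternative, but the
participation table the procedure reports is defined per training fold,
which is consistent with ranking once. The inner LOO then scores every
(C, gamma, ROI count) triple; the selected pair is the accuracy maximum
with ties resolved toward smaller C, then smaller gamma (prefer simpler
models), and the *peak region* is every ROI count attaining that maximum.
The held-out subject is predicted by each peak-count classifier and a
majority vote, ties going to the class with the larger mean decision value.
Reported: outer accuracy/sensitivity/specificity, the mean inner-CV
accuracy (kept separate because "CV accuracy" is ambiguous between tiers),
and mean ± sd of the peak ROI count.

Hyperparameter grids are configurable; the full defaults are
`C = 2^{-5..15}` and `gamma = 2^{-15..3}` in steps of 4×. The desk-scale
analyses use `C in {1, 10}` and `gamma = 1`: after unit normalization the
squared distances lie in [0, 4], so gamma near 1 is the natural scale, and
the reduced grid keeps a full 70-subject nested LOO (70 outer × 69 inner
folds × grid × ROI counts) around a minute on one CPU. The problem sizes
used by the tests and the acceptance script — 10 regions × 4 voxels for
classification, 30 regions for network analysis, 10 cohort draws, B = 99
permutations — are the package's desk-scale study conditions.

## Permutation significance

`balanced_permutations()` draws B label shuffles preserving class counts
exactly (sampling with replacement across sets, so duplicate label vectors
may occur — the natural reading of balanced resampled label sets;
resampling *subjects* would change the design). The null run keeps the two
deliberate simplifications of the original: hyperparameters stay fixed at
the real-label selection, and each permutation's statistic is the outer-LOO
accuracy *maximized over ROI counts* along the (per-fold, permuted-label)
ranking. The maximum makes the null values stochastically larger than any
matched single-count statistic, so the resulting p is conservative. The
estimator is the add-one `(1 + r)/(B + 1)`, which is a valid finite-sample
p-value, can never be zero, and at B = 1000 is consistent with a "p below
0.001" claim only when the observed statistic beats every null value.

## Complex-network analysis

Per subject, the ROI-mean band-limited series give a Pearson correlation
matrix; negative and self correlations are pruned to zero. Proportional
thresholding keeps the top `ceiling(alpha * n(n-1)/2)` positive weights —
the quota is a fraction of all possible node pairs (the alternative,
a fraction of surviving positive edges, is a config choice away in the
sense that callers may pre-prune); ties break toward the lexicographically
smaller pair, making the edge sets nested along any alpha grid.

Metrics on the binary graph: degree; per-node clustering (triangle
fraction, 0 for degree < 2); per-node path length as the mean of *finite*
shortest-path distances with unreachable pairs excluded and counted (the
toolbox conventions vary here; exclusion plus an explicit disconnection
count was chosen so sparse graphs remain comparable); the characteristic
path length as the mean of node values; binary assortativity as the
Pearson correlation of end-node degrees over the directed edge list
(undefined for regular graphs — returned as NA with a warning). The
small-world ratio is `sigma = (C/C_rand)/(L/L_rand)` against
degree-preserving rewired nulls (10 swap attempts per edge, 20 nulls by
default, computed on the largest component).

The analysis threshold is selected by maximizing the across-subject
`mean(sigma)/sd(sigma)` (sd with denominator n−1) over a grid, default
`{0.05, ..., 0.50}`; ties go to the smaller alpha, a zero sd yields a
capped (1e12) ratio with a log note, and any alpha where some subject's
ratio fails (too sparse to rewire) is skipped and logged. Group tests are
Welch t-tests — matching the unequal-variance treatment used elsewhere in
the pipeline — with Benjamini–Hochberg correction over the four motor ROIs
(left/right M1 and SMA) per local metric, and over threshold-grid points
for the global assortativity.

The planted-optimum construction used to validate the threshold criterion
(`simulate_planted_threshold_graphs()`) gives every subject an identical
strong backbone of exactly `ceiling(alpha* n(n-1)/2)` edges (ring lattice
plus fixed shortcuts) and subject-specific weaker weights with a random
module structure of random granularity. At `alpha*` every subject retains
exactly the backbone, so the sigma spread collapses to rewiring noise; above
it the retained topologies diverge (module structure), below it random
backbone subsets differ. The criterion's ratio therefore peaks at `alpha*`
for a genuine, construction-level reason rather than by tuning.

## Group maps

Voxelwise Welch t statistics (Welch–Satterthwaite degrees of freedom,
two-sided p — the procedure reports both increases and decreases) are
thresholded at p = 0.001 with a minimum cluster extent of 5 voxels, the
display convention adopted as default. Familywise correction is a
permutation maximum-cluster-extent test (add-one estimator over label
permutations), replacing random-field theory: on desk-scale synthetic maps
there is no smoothness to estimate and the permutation test gives exact
familywise control under exchangeability. Voxel adjacency is pluggable —
chain adjacency for the 1-D voxel strips of the synthetic cohorts,
6-connectivity `grid_adjacency()` for volumetric exports.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → preprocess → features → classify →
permtest → cna → groupstats from one config; a stage whose inputs are
missing halts the run naming the stage. One global seed derives per-stage
seeds by hashing the stage name (`stage_seed()`), so any stage can be rerun
in isolation with identical results; the report and the verbatim config are
serialized as JSON. The numbered scripts under `analysis/` are thin
narrative drivers over the same exported functions and hand data to each
other through `results/`.

## Known limitations

* The alternating MKL optimization is a surrogate for an incompletely
  specified original; it preserves the testable properties (simplex
  weights, summed kernel, SVM reduction at M = 1, margin-norm ranking) but
  need not reproduce the original's exact weights.
* The fixed-point weight update can concentrate all mass on one kernel for
  strongly separable data; this is expected behavior of margin-norm
  weighting, not an error state.
* Desk-scale cohorts use few voxels per region, so the per-ROI PCA often
  runs at or near full rank; conclusions about PCA truncation behavior at
  ~467 voxels per region do not follow.
* `cohort`-mode PCA leaks across folds by design fidelity; use
  `fold_safe` for unbiased error estimates.
* The permutation cluster correction assumes exchangeability of subjects
  under the null, which holds for the synthetic cohorts but is an
  approximation under real between-group variance differences.
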