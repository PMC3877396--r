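# mklconn

Systems-level resting-state fMRI biomarker analysis for motor network
disease (the motivating case is amyotrophic lateral sclerosis): seed-based
motor functional connectivity features, a multiple-kernel-learning (MKL)
support vector machine with one RBF kernel per atlas region, recursive
kernel elimination, two-tiered leave-one-out cross-validation with
peak-region majority voting, a balanced permutation null, and
complex-network analysis of the parcellated connectivity graphs. A
synthetic cohort generator with planted group-level connectivity effects
makes every stage testable without scan data.

## Who this is for

Researchers building classification-based biomarkers from resting-state
BOLD connectivity who want (a) the full per-ROI MKL pipeline as reusable,
tested functions, and (b) a simulation harness in which the recovery of
planted effects — classifier accuracy, network-metric group differences,
threshold selection — can be verified end to end.

## The model in brief

Per subject, preprocessed series (16-regressor nuisance regression with
motion/CSF/WM and derivatives, linear detrend, zero-phase order-4
Butterworth band-pass to 0.03–0.06 Hz) yield 24 seed correlation maps
(12 motor seeds per hemisphere). Maps are reduced by anatomical ROI with
across-subject PCA to *k* scores per (seed, ROI) — at full scale
116 × 24 × 10 = 27,840 features. Each ROI's features define an RBF kernel
K_m; the classifier learns simplex weights d on K = Σ_m d_m K_m by
alternating between the soft-margin SVM dual (SMO, in C++) and the
multiplicative update d_m ∝ d_m √S_m, where S_m = d_m (αy)ᵀK_m(αy) is the
kernel's share of ‖w‖² = Σ_m S_m. Recursive elimination of the
smallest-S_m kernel ranks ROIs; a nested LOO selects (C, γ) and all ROI
counts at the inner-accuracy peak, whose classifiers vote on each held-out
subject. Significance comes from balanced label permutations with fixed
hyperparameters and the accuracy maximized over ROI counts (a deliberately
conservative null, p = (1+r)/(B+1)). Connectivity graphs (pruned Pearson
matrices, proportional threshold chosen by maximizing mean/sd of the
small-world ratio σ = (C/C_rand)/(L/L_rand) across subjects) are compared
between groups on degree, path length and binary assortativity with Welch
t-tests under Benjamini–Hochberg FDR; voxelwise Welch t-maps get
permutation cluster-extent correction.

## Worked example

```r
library(mklconn)
spec <- desk_cohort_spec("classification", seed = 7,
                         n_patients = 10, n_controls = 10)
cohort <- generate_cohort(spec)
cohort <- preprocess_cohort(cohort)
features <- pca_reduce_maps(cohort_seed_maps(cohort), k = 3)
cv <- nested_loo_evaluate(features, cohort_labels(cohort),
                          C_grid = c(1, 10), gamma_grid = 1)
print(cv)
perms <- balanced_permutations(cohort_labels(cohort), B = 99, seed = 8)
nd <- null_distribution(features, cohort_labels(cohort), perms,
                        C = median(cv$selected_C), gamma = 1,
                        observed = cv$accuracy)
print(nd)
```

Output:

```
nested LOO: accuracy 100.0% (inner CV 100.0%), sensitivity 100.0%, specificity 100.0%
ROIs at peak discrimination: 4.8 +/- 1.3
permutation null: observed accuracy 1.000, B = 99, p = 0.02
```

The cohort carries strong planted effects (hyper-coupled subcortical motor
regions, decoupled subcortical–cortical and motor–non-motor pairs), so the
nested LOO separates the groups perfectly; about 5 of the 10 ROIs are
needed at peak discrimination, and the permutation p sits at its B = 99
floor of 1/(B+1)·2 — the observed accuracy beat all 99 balanced-relabel
nulls. With `desk_cohort_spec("null")` (no planted effects) the same
pipeline stays at chance and the permutation p is non-significant, which
is the no-leakage check.

The numbered scripts under `analysis/` run the same stages as a file-based
workflow (simulate → preprocess → features → classify → permutation test →
network analysis → group maps), writing their tables under `results/`;
`run_pipeline()` does the same in one call from a config object.

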