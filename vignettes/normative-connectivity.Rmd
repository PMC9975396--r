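---
title: "Normative modeling of functional brain network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modeling of functional brain network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Psychiatric disorders are heterogeneous: two patients with the same
diagnosis can deviate from "typical" brain organization in different
ways, which is one reason case-control classifiers transfer poorly to
clinical practice. Normative modeling turns the question around: instead
of separating groups, it learns a model of *healthy* variation only, and
quantifies how far each individual deviates from that norm.

`normfc` implements this idea for inter-network functional connectivity
(FC). Each subject is summarized by the Pearson correlations between the
BOLD time series of 14 canonical functional brain networks (FBNs). The
correlation matrix is symmetric with unit diagonal, so the strict lower
triangle — 91 network-pair features — carries all the information; it is
vectorized in a fixed, documented row-major order (`pair_index()`), and
`devectorize()` restores the matrix layout exactly.

Features are standardized per pair,

$$z = \frac{x - \mu}{\sigma},$$

with $\mu$ and $\sigma$ the mean and *population* standard deviation
(divide by $n$) computed from the healthy training subjects only; the
same parameters are then applied to every set, so no information leaks
from test to train. The SD convention is not forced by the method; we
fix the population convention and the two-subject example
$\{0, 2\} \mapsto \mp 1$ in the tests pins it down.

The normative model itself is a fully connected autoencoder,
91–46–13–46–91: hidden layers use leaky-ReLU activation (negative slope
0.01), the output layer is linear because targets are standardized
reals, weights start from He fan-in normal initialization, and training
minimizes mean squared reconstruction error with an L2 penalty of
$10^{-5}$ on all weight matrices and dropout 0.5 after each hidden
activation, for exactly 1000 epochs of minibatch Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$, learning
rate $5\times10^{-4}$). The implementation is plain R matrix algebra —
the network is small enough that a framework would add nothing — and a
single seed controls initialization, dropout masks and batch shuffling,
so training is bit-reproducible on a fixed platform.

Deviation is measured at two resolutions. Per subject,

$$\mathrm{MSE}_s = \frac{1}{91}\sum_{i=1}^{91}(\hat y_i - y_i)^2,$$

and per network pair within a test group of $N$ subjects,

$$\mathrm{MSE}_f = \frac{1}{N}\sum_{i=1}^{N}(\hat f_i - f_i)^2.$$

The two are linked by a conservation identity — the subject-mean of
$\mathrm{MSE}_s$ equals the feature-mean of $\mathrm{MSE}_f$ (both are
the grand mean of squared residuals) — which the pipeline asserts to
1e-10 on every run as an internal consistency check.

## The analysis pipeline

`run_pipeline()` chains the stages: simulate (optional), connectivity,
standardize + train, and then the deviation analyses:

* **Group comparison.** $\mathrm{MSE}_s$ medians per test group;
  Shapiro–Wilk normality p-values are reported (never used to gate) and
  group differences are tested with a two-sided Mann–Whitney U test.
  For $\min(n_1, n_2) \le 8$ the permutation null is enumerated
  exhaustively with midranks, so ties are exact; larger samples use the
  tie-corrected normal approximation. No multiple-testing correction is
  applied across the handful of comparisons; p-values are reported raw.
* **Binarized deviation graphs.** The per-feature absolute differences
  $|\hat y - y|$ (standardized units) of *all* test subjects are merged,
  and the 80% quantile (linear-interpolation) becomes the binarization
  threshold: values at or above it are "retained" (the top 20%). Each
  subject's thresholded vector becomes a 14-node graph; node degrees
  (0–13) count deviant connections per network, summarized per group by
  the median degree and its histogram (unit bins over 0–13).
* **Worst-reconstructed pairs.** Per group, the
  $\lfloor 0.10 \times 91\rfloor = 9$ pairs with the largest
  $\mathrm{MSE}_f$; ties break by descending value then ascending pair
  index, so selections are deterministic. The healthy test group's
  $\mathrm{MSE}_f$ matrix is subtracted from each patient group's to
  remove pairs that are poorly reconstructed even in health.
* **Characteristic pairs.** The analysis is repeated under two
  healthy-split conditions: (a) the default split, and (b) a doubled
  healthy test set, realized by deterministically moving the tail of the
  training pool into the test set and *retraining from scratch* (the
  published procedure strongly implies, but does not state, retraining;
  we retrain because the condition changes the training set). A pair
  characterizes a patient group if, under both conditions, it is in the
  top-10% both before and after subtraction (rule 1) or only after
  (rule 3). Pairs highlighted only before subtraction (rule 2) are
  reported separately as non-characteristic.
* **Individual level.** The absolute differences at the characteristic
  pairs, per subject, plus a flag for subjects exceeding the healthy
  median at half or more of those pairs — a minimal heterogeneity
  summary.
* **Generalization.** `score_independent_cohort()` applies a trained
  model — with its stored standardizer and stored binarization
  threshold — to a second cohort it never saw, mirroring evaluation on
  an independent dataset. The stored threshold is reused (rather than
  re-estimated) so the independent cohort is scored on the training
  run's scale.

Motion QC implements the rejection rule for 3 mm voxels: exclude when
maximum framewise displacement exceeds 3 mm, any translation exceeds
3 mm, or any rotation exceeds 3°. "Exceeds" is strict — a value of
exactly 3 passes. When a motion table lacks an FD column it is computed
Power-style: the sum of absolute backward differences of the six rigid
parameters, rotations converted to arc length on a 50 mm sphere (the
source protocol does not define its FD formula; this is the most common
choice, and the thresholds are configurable).

## The synthetic cohort generator

The raw inputs of the original analysis are controlled-access fMRI
datasets behind a heavy preprocessing chain, so the package ships a
generator for the *downstream product*: multi-subject network time
series with known structure.

* **Population template.** A block-structured 14×14 correlation matrix
  (functional families: salience, auditory/language, default mode,
  visual, executive, basal ganglia, sensorimotor; within-block 0.5,
  between 0.1, light seeded roughening), projected to the nearest valid
  correlation matrix (Higham-style alternating projections via
  `Matrix::nearPD`, then exact diagonal rescaling). Every emitted
  template is symmetric, unit-diagonal and positive definite.
* **Patient groups.** Group-level abnormality is a set of injected edge
  offsets; the default is three pairs per group at $\delta = +0.4$,
  chosen among pairs reported abnormal for each disorder
  (schizophrenia-like: ASN-BGN, BGN-HVN, HVN-RECN; bipolar-like:
  BGN-DDMN, BGN-LN, HVN-PVN; ADHD-like: ASN-LN, ASN-PN, LN-RECN). The
  truth manifest records them for recovery checks.
* **Subject variability.** Individual FC does not scatter independently
  edge by edge: individual differences are trait-structured, and some
  pairs are far less stable across healthy people than others. The
  generator therefore draws each subject's deviation from a low-rank
  model (`fc_variability()`): two latent factors load on every pair
  (shared SD 0.15), plus pair-specific Gaussian noise (SD 0.05), with
  four designated unstable pairs (HVN-LN, LN-SN, PN-VDMN, ASN-LN —
  pairs reported variable even among healthy subjects) at five times
  the pair-specific noise. The factor component is what a normative
  model *can* learn from other pairs; the pair-specific component is
  irreducibly individual. Without this structure, standardization makes
  every pair equally unpredictable and no stable "hard pairs" exist —
  a qualitatively wrong world for this analysis. The loadings are fixed
  population structure (own seed), shared by every cohort drawn from
  the same template.
* **Time series.** Given the subject's (re-projected) correlation
  matrix, T time points are drawn i.i.d. multivariate Gaussian —
  Gaussianity is the matching assumption when Pearson correlation is
  taken as a sufficient description. The default T = 150 mirrors the
  shortest common acquisitions (150–300 volumes). Columns are
  standardized (cosmetic; Pearson r is scale-invariant).
* **Determinism.** One master seed; subject $i$ draws from seed
  $(\text{master} + 1000003\,i) \bmod (2^{31}-2) + 1$, so enlarging a
  cohort never reshuffles existing subjects, and identical configs give
  byte-identical outputs.

What the generator does **not** emulate: scanner physics, hemodynamics,
physiological noise, ICA unmixing, site/batch effects, or any
within-network (voxel-level) structure. Passing tests therefore show
that the *pipeline* recovers known abnormalities under a plausible
statistical model of FC — not that the method overcomes real-data
confounds such as residual motion or site differences.

## Defaults and the reasoning behind them

| parameter | default | why |
|---|---|---|
| training subjects | 200 | healthy pool of the study conditions |
| test group size | 30 | per-group size of the study conditions |
| time points T | 150 | shortest common acquisition length |
| injected offset $\delta$ | +0.4 | detectable but within correlation bounds |
| shared (factor) SD | 0.15 | typical across-subject FC dispersion, mostly trait-structured |
| pair-specific SD | 0.05 (×5 unstable) | small irreducible edge noise; unstable pairs dominate their own variance |
| epochs | 1000 | fixed training protocol |
| learning rate | 5e-4 | fixed training protocol (Adam) |
| dropout | 0.5 | fixed training protocol |
| L2 penalty | 1e-5 | fixed training protocol |
| batch size | 8 | see below |
| leaky slope | 0.01 | common default; unspecified in the protocol |
| degree threshold fraction | 0.20 | top fifth of merged deviations |
| pair-selection fraction | 0.10 | 9 of 91 pairs |

Batch size is the one training hyper-parameter the protocol leaves
open. With 200 training subjects and the epoch budget fixed at 1000,
batch 32 yields only ~7000 Adam steps and visibly under-converged
models (healthy-test reconstruction error far above the level the
architecture can reach); batch 8 yields ~25,000 steps and converges
stably at negligible extra cost for a network this size. We therefore
default to 8 (configurable).

Other points where the method description is open, and what we fixed:

* **Vectorization order** is unspecified; we fix row-major strict lower
  triangle and persist the pair-index map with every feature file, so
  results are order-robust.
* **"Balancing" the two model-selection metrics** (mean of per-fold
  median train error; train-validation gap, both min-max normalized
  across candidates) is implemented as the argmin of their sum; the
  rule is a pluggable function argument.
* **Quantile/tie conventions.** The merged threshold is the
  linear-interpolation (type 7) quantile; ties at the threshold are all
  retained and the realized retained fraction is logged, because with
  discrete data "the top 20%" is not exactly attainable.
* **Cross-validation stratification** keeps dataset (site) proportions
  similar across the 10 folds via shuffled round-robin within label;
  labels smaller than the fold count fall back to best-effort
  assignment with a warning.
* **Degenerate inputs** fail loudly and specifically: zero-variance
  time-series columns name the network, zero-SD features name the
  feature, non-finite training loss names the epoch, and all-identical
  group comparisons report p = 1 with a warning rather than NaN.

## Problem sizes in the test suite

The stochastic end-to-end properties (patient deviation, injected-pair
recovery, cross-cohort overlap) are checked over ten master seeds at
the full default conditions — 200 + 4×30 subjects, 1000 epochs — which
takes a few minutes; structural tests run on deliberately small cohorts
(tens of subjects, tens of epochs) because they assert bookkeeping, not
learning. The Mann–Whitney null calibration uses 1000 simulations at
n = 20 per group.

## Known limitations

* The generator's dispersion parameters are order-of-magnitude choices;
  no public calibration of healthy FC dispersion at this network
  resolution was available to fit them.
* Reconstruction-based deviation confounds "abnormal" with "rare but
  healthy"; the healthy-subtraction step mitigates but cannot remove
  this, as the rule-2 pairs illustrate.
* Condition (b) changes both the training set and the healthy baseline
  at once; differences between conditions mix sampling and training
  variability by design.
* Determinism holds for a fixed platform/BLAS; exact bit-reproducibility
  across different linear-algebra backends is not guaranteed.
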