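---
title: "Individual morphological covariance networks and CNN classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological covariance networks and CNN classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`morphnet` implements a complete pipeline for classifying autism spectrum
disorder (ASD) against typical controls (TC) from structural MRI-derived
gray-matter (GM) volume maps:

1. **Network construction** — for each subject, the GM value distribution of
   every atlas parcel is estimated by kernel density estimation (KDE), and
   every pair of parcels receives an edge weight equal to the
   KL-divergence-based similarity (KLS) of their distributions. With a
   116-parcel SRI24-style atlas and the eight cerebellar vermis parcels
   (labels 109–116) excluded, this yields one symmetric 108 × 108 matrix per
   subject.
2. **Classification** — the matrices are treated as single-channel images
   and classified by a five-stage bottleneck residual CNN trained with Adam
   on binary cross-entropy under a nested 10-fold cross-validation plan.
3. **Interpretation** — Grad-CAM importance maps are computed for correctly
   classified ASD test subjects, fused, and thresholded at mean + 3SD to
   select the connectivities that drive the classification.
4. **Evaluation** — accuracy, sensitivity, specificity, F1 and ROC/AUC;
   conventional baselines (random forest, SVM, gradient boosting,
   autoencoder) on the flattened 11,664-feature vectors; and a label-flip
   permutation test of the observed accuracy.

A synthetic-data module generates parcellation atlases and multisite GM
cohorts with controllable group effects, so the full pipeline is testable
end to end without any imaging download.

# The network model

## Per-region densities

Within region $r$, the voxel values $v_1, \dots, v_n$ are summarized by a
Gaussian-kernel density evaluated on a grid $g_1 < \dots < g_G$ shared by
all regions of the subject:

$$ f_h(g) = \frac{1}{nh} \sum_{j=1}^{n} K\!\left(\frac{g - v_j}{h}\right),
\qquad P(g) = \frac{f_h(g)}{\sum_{g'} f_h(g')} . $$

Two published formulations of this construction exist: one indexes the
kernel sum by region (one value per ROI), which would give every region a
single scalar and make interregional divergences degenerate; the other —
the one adopted here — estimates each region's density from the voxel
values *within* it, which is the only reading under which the divergence
between two regions is well defined. The normalization turns the sampled
density into a discrete probability distribution over the grid, which is
what the divergence below consumes.

## Divergence and similarity edges

For two regions with discretized distributions $P$ and $Q$ on the same
grid, the symmetrized Kullback–Leibler divergence is

$$ D(P, Q) = \sum_{g} \left[ P_g \ln\frac{P_g}{Q_g}
   + Q_g \ln\frac{Q_g}{P_g} \right] \ge 0, $$

and the edge weight is the similarity $\mathrm{KLS}(P, Q) = e^{-D(P,Q)} \in
(0, 1]$: identical distributions score 1; the similarity decays
exponentially in the divergence. The diagonal is set to 1 exactly
($D(P,P) = 0$) rather than recomputed.

## Numerical choices

* **Grid**: $G = 128$ equally spaced points spanning the subject's pooled
  retained-region value range, padded by 3 bandwidths (`grid_pad`) on each
  side so essentially all kernel mass is covered. $G$ trades resolution
  against cost; 128 points resolve the Gamma-like value distributions the
  generator produces and real GM maps exhibit.
* **Kernel and bandwidth**: Gaussian kernel with Silverman's rule-of-thumb
  bandwidth per region (`stats::bw.nrd0`), the standard default when no
  bandwidth is prescribed. A fixed numeric bandwidth can be set in
  `network_config()` for reproducibility studies. Zero-variance samples
  fall back to a small fixed bandwidth with a warning.
* **Probability floor**: raw densities are floored at $\varepsilon =
  10^{-10}$ *before* normalization so the logarithms in $D$ are finite even
  where a region has no mass; $\varepsilon$ is far below $1/G$, so the
  floor is numerically invisible wherever a density is appreciable.
* **Ordering**: rows/columns are sorted by ascending atlas label after
  exclusion, so the region ↔ matrix-index map is deterministic — required
  for reporting Grad-CAM edges back as region pairs.
* **Pairwise computation**: all $108^2$ divergences reduce to one
  cross-entropy Gram matrix ($P \log P^\top$), so network construction is a
  single BLAS product per subject; an explicit-loop oracle in the test
  suite confirms equality to 1e-10.

# The classifier

The model is a serial stack of five bottleneck residual stages. Stage $s$
maps $C_{s-1}$ channels to $C_s = (16, 32, 64, 128, 256)_s$ through a
stride-2 1×1 reduction to $C_s/4$ channels, a 3×3 convolution, and a 1×1
expansion, with batch normalization after every convolution and before
activation, and a projection shortcut (1×1, stride 2, batch-normalized)
added to the branch output before the stage ReLU: $F(X) + X$. Spatial sizes
run 108 → 54 → 27 → 14 → 7 → 4; a global average pool and a single sigmoid
unit produce the ASD score, and no dropout is used anywhere. The input
matrix is fed raw — no cropping, flipping, or augmentation, since a
connectivity matrix has no photometric invariances.

Design points that the architecture description leaves open, resolved here:

* **Channel widths** 16–256 with bottleneck factor 4 keep the model
  CPU-trainable at 108 × 108 while preserving the five-bottleneck stride-2
  design; exact widths are declared in `model_config()` and can be changed.
* **Stride placement**: the stride sits on the 1×1 entry convolution of
  each bottleneck, so the 3×3 transform operates at the reduced resolution.
  Both placements (entry 1×1 vs 3×3) appear in the residual-network
  literature and give identical output shapes; the entry placement
  substantially reduces compute at full resolution.
* **Shortcuts**: projection (1×1 stride-2) whenever resolution or width
  changes — with these widths, every stage; an identity shortcut is used
  automatically if a stage preserves both.
* **Loss**: binary cross-entropy with predictions clamped to
  $[\delta, 1-\delta]$, $\delta = 10^{-7}$, so saturated outputs keep the
  loss finite.

The engine (im2col convolutions, batch norm, Adam) is implemented in the
package with small compiled kernels for the memory-bound elementwise steps;
the backward pass is verified against central finite differences to 1e-5 in
the test suite for every layer type.

## Cross-validation protocol

`make_cv_plan()` reproduces the nested protocol: per repeat, all subjects
are randomly partitioned into 10 equal groups $S_1, \dots, S_{10}$; $S_{10}$
is the test set; the remaining subjects are repartitioned into 10 subgroups,
one of which is the validation set for early stopping and the other nine
the training data. Each of the 20 repeats re-randomizes both partitions —
the protocol fixes the *name* of the test group, but because the partition
is freshly random per repeat this is equivalent to a random fold, and it is
implemented literally. `train_cnn_cv(test_folds = "all")` additionally
rotates every fold through the test role, which desk-scale runs use to pool
predictions over all subjects.

## Hyperparameters

The reference protocol's values are the defaults: Adam, learning rate 1e-5,
minibatch 32. The epoch budget is not stated anywhere; the validation
subgroup exists precisely for early stopping, so `fit_cnn()` stops after
`early_stop_patience` epochs without validation-loss improvement and
restores the best parameters. Desk-scale runs in the tests and the
acceptance script use learning rate 1e-3 with 5–15 epochs: a rate of 1e-5
is appropriate for many passes over a thousand-subject cohort but cannot
move the loss measurably within a reduced epoch budget, so scaling the rate
with the budget is the package's own choice for small synthetic cohorts
(the problem sizes used there are n = 200 for the signal-recovery check,
n = 120 for the null check, and n = 30 per repeat for permutation
calibration).

# Grad-CAM

For a trained model and one input, the channel weights are the spatially
averaged gradients of the class score with respect to the final stage's
post-ReLU activations $A^k$ (4 × 4 here):

$$ \alpha_k = \frac{1}{Z} \sum_{i,j} \frac{\partial y}{\partial A^k_{ij}},
\qquad L = \mathrm{ReLU}\Big(\sum_k \alpha_k A^k\Big), $$

with $y$ the pre-sigmoid logit for ASD (its negation for TC — under a
single sigmoid output the two class scores are antipodal). Because the head
is a global average pool plus a linear unit, the gradient is exact and
cheap; the test suite still checks it against a finite-difference oracle.
$L$ is upsampled bilinearly (half-pixel-centered) from 4 × 4 to 108 × 108 —
the standard choice where only "upsampling" is specified. The coarse 4 × 4
source resolution means localization is at the granularity of ~27-row
blocks of the matrix; this is inherent to the method, not an artifact.

Fusion and selection follow the reported procedure with the unstated
details resolved as: maps of *test-set subjects whose true label is ASD and
whose prediction is correct* are averaged element-wise (the minimal fusion
operator), symmetrized as $(M + M^\top)/2$ because edges are unordered
pairs, and thresholded at mean + $k$·SD ($k = 3$) computed over the
upper-triangle off-diagonal entries of the fused map (the diagonal is
constant 1 in the inputs and self-similarity is not a connectivity). Edges
strictly above threshold are reported with their region labels. The
threshold is scale-invariant: multiplying all maps by a positive constant
selects the same edges.

# Evaluation

ASD is the positive class throughout: sensitivity is the ASD detection
rate. Confusion metrics use a 0.5 threshold on the sigmoid score
(unspecified upstream; 0.5 is the neutral choice), AUC uses the raw scores
with ties counted 1/2. Metrics whose denominator is empty are `NA`, never
0. Baselines (random forest via `ranger`, RBF SVM via `e1071`, gradient
boosting via `xgboost`, and an autoencoder with a 11,664 → 512 → 64 encoder
pretrained by reconstruction and a ridge-logistic head on the frozen latent
features) consume the flattened 108 × 108 = 11,664-feature vectors under
the identical fold assignments as the CNN.

## Permutation test

The reference protocol flips 20% of the labels uniformly at random in each
of 5,000 iterations and retrains; the empirical p-value is
$(1 + \#\{\mathrm{null} \ge \mathrm{observed}\})/(1 + n_\mathrm{perm})$.
This label-*flip* (rather than full-permutation) null is implemented
literally; a full permutation can be obtained by passing permuted labels to
any `fit_eval`. Since thousands of CNN retrainings are not a desk-scale
operation, `make_surrogate_fit_eval()` provides a fast surrogate: a
ridge-regularized linear scorer on the flattened features fitted in kernel
(Gram) form, so the Gram matrix and fold split are computed once and each
iteration costs one small linear solve. Under label permutation the
statistic remains exchangeable, which is the property the calibration of
the test rests on; the test suite verifies that null-cohort p-values are
approximately uniform. Full CNN retraining can be plugged in through the
`fit_eval` handle unchanged.

# The synthetic-data generator

The generator emulates the *preprocessed* inputs of the real pipeline — a
labeled template-space parcellation and per-subject GM value maps — not raw
T1-weighted images (registration, bias-field and tissue segmentation are
upstream of this package's inputs and out of scope).

* **Atlas**: region seeds on a jittered lattice, nearest-seed (Voronoi)
  assignment — spatially compact parcels that jointly cover the grid, every
  label present, ≥ 30 voxels each, bit-reproducible per seed. The default
  geometry is a 48³ grid with 116 regions.
* **Values**: within region $r$, voxel values are Gamma(shape $k_r$, scale
  $\theta_r$) with $k_r \in [2.5, 3.5]$ and $\theta_r \in [0.2, 0.4]$ drawn
  once per cohort — skewed positive values that mimic GM density maps and
  give each region a full distribution for KLS to compare.
* **Group effect**: in the ASD group, the scale of the first member of each
  affected pair is multiplied by $e^{+s}$ and the second by $e^{-s}$, with
  $s$ the `shift_magnitude`. The opposite signs are deliberate: two regions
  shifted identically would keep their *mutual* KLS unchanged, so the edge
  between pair members would carry no signal. $s = 0$ makes the groups
  identically distributed (verified by an exact-level test in the suite).
  The default $s = 0.6$ with six affected pairs represents a strong,
  clearly learnable effect; it is a synthetic stand-in, not a claim about
  the effect size of ASD biology.
* **Sites**: an additive per-site constant on all regions' scales
  reproduces multisite heterogeneity orthogonal to diagnosis; subject-level
  variability is a log-normal jitter (`noise_sd`, default 0.1) on every
  region's scale.
* **Seeds**: one master seed; region parameters and each subject use
  deterministically derived streams.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline recovers distributional group differences planted at the
region level, that its null behavior is calibrated, and that every printed
structural number (108 × 108 matrices, 11,664 features, 8 excluded parcels)
is reproduced. They do not demonstrate performance on real multisite MRI,
where registration error, segmentation noise, site-by-diagnosis
confounding, and far subtler effect sizes dominate; headline accuracies on
real cohorts are therefore not targets of the synthetic evaluation.

# Known limitations

* The CNN engine is single-threaded CPU code; it is sized for 108 × 108
  inputs and desk-scale cohorts, not for large imaging studies.
* The autoencoder baseline is intentionally small and trained briefly; it
  is a comparison point, not a tuned competitor.
* Grad-CAM localization is limited by the 4 × 4 resolution of the final
  stage; conclusions about individual edges inherit that coarseness.
* The label-flip null perturbs only 20% of labels, so its null
  distribution is narrower than a full-permutation null; this matches the
  reference protocol but should be kept in mind when interpreting p-values.
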