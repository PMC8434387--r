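---
title: "Methods: dual-branch attention networks for imbalanced IMU activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-branch attention networks for imbalanced IMU activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neck-mounted inertial measurement units (IMUs) on animals record triaxial
acceleration and triaxial angular velocity at 100 Hz.  Cut into 2 s windows,
each labeled sample is a pair of $3 \times 200$ arrays (axes $\times$
timesteps) plus an activity label — here the six equine activities eating,
standing, trotting, galloping, walking under a rider, and walking without
one — and a subject (animal) identity.  Two features of such data drive the
design of this package:

* **Two modalities.** Accelerometer and gyroscope carry partly redundant,
  partly complementary information.  Early fusion (stacking channels) mixes
  distributions; late fusion (averaging decisions) discards cross-modal
  structure.  The model here extracts modality-specific features in two
  convolutional trunks and lets them interact through an attention module.
* **Class imbalance.** Activity budgets are skewed; in the reference horse
  dataset the largest class (walking with rider, 38.94%) outnumbers the
  smallest (walking without rider, 3.80%) by a factor 10.25.  Ordinary
  cross-entropy training then sacrifices minority-class recall, which is
  often the scientifically interesting quantity.

## Architecture

Each modality trunk is four *residual-like convolution blocks* separated by
three max-pooling layers.  A block computes

$$X_{l+1} = \mathrm{ReLU}\big(\mathrm{BN}(\mathrm{Conv}_{1\times1}(X_l))
  \oplus \mathrm{BN}(\mathrm{Conv}_{1\times3}(X_l))\big),$$

an elementwise sum of a pointwise channel-mixing path and a temporal path
(kernel 1 along the axis dimension, 3 along time, zero-padded so length is
preserved).  Every convolution is followed by batch normalization.  Pooling
(kernel and stride 2) acts only along time — $200 \to 100 \to 50 \to 25$ —
never across the three sensor axes, so axis identity survives to the top of
the network and attention maps remain interpretable per axis.  After the
fourth block, global average pooling over time and axes yields one vector
per modality, each passes a fully connected layer with ReLU, the two vectors
are concatenated, and a joint fully connected layer emits the six logits.

### Cross-modality interaction module

Let $A, G \in \mathbb{R}^{C \times H \times W}$ be the two trunks' feature
maps at the insertion site ($H = 3$ axes, $W$ timesteps).  The module
averages each over channels, giving two $1 \times H \times W$ spatial maps,
concatenates them, and fuses them into a joint representation

$$Z = \mathrm{ReLU}\big(\mathrm{BN}(\mathrm{Conv}_{1\times3}
  [\mathrm{avg}(A), \mathrm{avg}(G)])\big) \in
  \mathbb{R}^{C' \times H \times W}.$$

Two *independent* $1\times3$ convolution heads (never sharing weights) map
$Z$ to one sigmoid attention map per modality,
$\alpha_A, \alpha_G \in (0,1)^{1 \times H \times W}$, which recalibrate the
inputs residually:

$$A' = A \otimes \alpha_A \oplus A, \qquad G' = G \otimes \alpha_G \oplus G,$$

with the map broadcast over channels.  Two algebraic consequences are worth
stating because the tests rely on them: $A' - A = A \otimes \alpha_A$ holds
to machine precision, and since $\alpha_A \in (0,1)$ the module can only
amplify a feature by a factor in $(1, 2)$, never null it — attention is a
soft gain, not a mask.  With zero-initialized heads $\alpha \equiv 1/2$ and
$A' = 1.5A$ exactly.

The module can sit after any of the three pooling layers (ablation variants
1–3), after the last block (the default — deep features carry more general
patterns and benefit most from recalibration), or be absent (variant 0).
All placements are shape-preserving.

### Defaults the figures do not pin down

Block widths (16, 32, 64, 128), the joint channel count $C' = 16$, and the
branch fully connected width 64 are package defaults chosen to double
channel width with depth as the architecture family conventionally does;
all are configurable.  Weight initialization is a seeded fan-in (He) normal
scheme; the seed is part of the model configuration so builds are
bit-reproducible.  There is no dropout anywhere: regularization is the L2
term of the training protocol.

## Losses for imbalanced training

With logits $z \in \mathbb{R}^C$ and one-hot label $y$:

* **Softmax cross-entropy** $-\log p_y$, the baseline.
* **Class-balanced focal loss**, the method of interest.  Logits of
  non-true classes are negated ($z_i^t = z_i$ if $i = y$, else $-z_i$), each
  class contributes a one-vs-rest sigmoid term with focal modulation, and
  the sum is scaled by the reciprocal *effective number* of the true class:

  $$L = \frac{1-\beta}{1-\beta^{n_y}} \sum_{i=1}^{C}
    (1 - p_i^t)^{\gamma} \big(-\log p_i^t\big), \qquad
    p_i^t = \sigma(z_i^t).$$

  The sum runs over **all** classes in the sigmoid (one-vs-rest) form — not
  softmax focal — and the class-balancing factor uses only the true class's
  count.  $\beta = 0.9999$ and $\gamma \in \{0.5, 1, 2\}$ (0.5 default) are
  the protocol settings.
* **Comparison losses**: cost-sensitive CE (sample weight $N/(C\,n_y)$),
  class-balanced CE (same CB weight on softmax CE), focal alone (CB weight
  replaced by 1), and adaptive class suppression (sigmoid CE whose
  non-true-class terms are weighted 1 toward commoner classes and by the
  predicted confidence $p_i^{\gamma}$ toward rarer ones).  The
  cost-sensitive and adaptive-suppression forms follow the standard
  formulations of their literature since the activity-recognition study
  names but does not restate them; they are reconstructions and documented
  as such.

### Weight normalization — a scale subtlety that matters

The effective number $(1-\beta^n)/(1-\beta)$ saturates at $(1-\beta)^{-1} =
10^4$.  With $\beta = 0.9999$ and class counts in the tens of thousands the
CB weights are gentle (ratios of ~3); with desk-scale counts of tens to
hundreds they become essentially $1/n_y$, shrinking the whole loss by two
orders of magnitude.  Adam is nearly scale-invariant, but the L2 penalty
gradient $\lambda w$ is *not* scaled along — at $\lambda = 0.1$ it then
dominates the data gradient and training collapses.  The package therefore
normalizes the per-class CB weights to mean 1 over classes
($w_c \mapsto w_c\,C/\sum_c w_c$), the convention of the reference
implementation of the class-balanced loss.  Relative class weighting is
untouched; at $\beta = 0$ the factor is exactly 1.  `normalize = FALSE`
restores the literal reciprocal-effective-number scaling.

All losses return batch means (configurable to sums) and expose exact
analytic gradients, verified against central finite differences in the test
suite.  The L2 term ($\lambda/2\,\lVert w\rVert^2$, gradient $\lambda w$,
$\lambda = 0.1$) is applied in the optimizer to convolution and fully
connected weights only — not biases or batch-norm affine parameters — with
a strict all-parameters mode available.

## Training and evaluation protocol

**Leave-one-subject-out.** Each animal serves once as the test subject; the
cyclically next subject validates; the rest train.  Standardization (per
axis per modality, pooled over all timesteps: subtract mean, divide by
population standard deviation) is fitted on the training subjects only and
applied to validation and test, avoiding leakage; a `global` scope
reproduces the alternative reading in which the whole pool is standardized
once.  Class counts for loss weighting likewise come from the training
subjects only.

**Optimization.** Adam (default $10^{-4}$ learning rate, decayed by 0.1
every 20 epochs; 100 epochs; batch 256 — the protocol defaults), shuffling
reseeded per epoch from the fold seed, last incomplete batch kept.  After
every epoch validation accuracy is computed; the parameters of the best
validation epoch are kept (earliest epoch on ties, favoring less-overfit
checkpoints) and evaluated once on the test subject.

**Metrics.** From the test confusion matrix (rows truth, columns
prediction): per-class one-vs-rest precision, recall and F1; overall values
are unweighted (macro) means over classes, accuracy is trace over total;
everything is reported multiplied by 100.  Accuracy is identically the
class-frequency-weighted mean of per-class recalls — a useful invariant
(tested on random matrices) explaining why rebalancing losses can raise
macro metrics while lowering accuracy.  A class never predicted gets
precision 0 with a warning.  Fold results pool by summing confusion
matrices; row-normalized (recall) and column-normalized (precision)
matrices are reported alongside pooled metrics, with per-fold averaging
available through the per-fold results.

**Prediction** is the argmax of the logits with ties broken toward the
lowest class index, deterministically.

## The synthetic data generator

No public data ships with the package; a generator produces labeled
multi-subject segment sets with the statistical structure the method
assumes.  Each class is a harmonic-plus-noise process on a latent gait
phase: class-specific fundamental frequency (standing 0.5 Hz, eating 1.1,
walking 1.4, trotting 2.5, galloping 3.4), harmonic weights, per-axis
amplitudes, Gaussian sensor noise (sd 0.3 by default).  The gyroscope
channel is a 90-degree phase-shifted, differently weighted transform of the
same latent process, mixed (via the `coupling` parameter, default 0.6) with
a class-specific complementary component, so concatenating modalities is
never worse than either alone.  Three qualitative facts of the motivating
study are engineered in: class shares default to the reference composition
(imbalance ratio 10.25); the two walking classes share frequency and
harmonic shape and differ only by a coherent 25% amplitude offset, so
confusion concentrates on that pair; and eating draws mix in a low-amplitude
walking component (grazing animals walk slowly while eating).

Subject effects are a log-normal amplitude multiplier per modality
(sd 0.1) and a fixed per-subject gait-frequency multiplier (±5%), drawn
before any segments so datasets are extensible without perturbing subject
identities; the whole dataset is a pure function of (config, templates).
Per-subject class counts follow largest-remainder rounding of the requested
proportions.  A per-segment phase jitter exists but defaults to zero, so a
noise-free, jitter-free configuration generates identical segments — a
deliberately degenerate regime used by the tests.

Worth knowing when interpreting results: the ±5% frequency drift
phase-decorrelates fast gaits across subjects over a 2 s window, which
defeats naive raw-signal nearest-neighbor matching while remaining easy for
the convolutional model — a qualitatively realistic property.  What the
generator does **not** emulate: gravity orientation, sensor drift,
magnetometer channels, label noise, activity transitions within a window,
or realistic spectra.  Tests passing on this data demonstrate the
machinery learns and rebalances as designed, not that it reproduces any
real-data accuracy figure.

## Numerical choices

* Batch normalization uses population (biased) variance for both
  normalization and running statistics (momentum 0.1, $\varepsilon =
  10^{-5}$); evaluation mode uses running statistics, making evaluation
  forward passes deterministic.
* Standardization uses the population standard deviation; a zero-variance
  axis gets $\sigma = 1$ substituted with a warning rather than an error so
  degenerate synthetic fixtures remain usable.
* Max-pool ties resolve to the earlier timestep; argmax ties to the lower
  class index.
* The temporal convolution is evaluated as one stacked BLAS product with a
  fused shifted accumulation; batch-norm forward/backward, pooling, and the
  shift pairs are single-pass compiled kernels.  Backward passes are exact
  analytic gradients, verified against finite differences through the full
  network (including attention and training-mode batch normalization).
* The interaction module draws its initial weights after the trunks, so
  configurations differing only in attention placement share identical
  trunk initializations under one seed — the property that makes the
  ablation comparison clean.

## Problem sizes used in the shipped studies

The package's own studies (test suite and acceptance script) run at reduced
scale chosen to exercise every mechanism on a single CPU: widths
(8, 16, 16, 32), joint channels 8, branch width 32; 6 subjects; 100
segments/subject balanced at noise 0.1 for the end-to-end learning check
(12 epochs, batch 64, Adam at $10^{-3}$ — the shorter schedule warrants a
larger rate than the 100-epoch protocol default); 120 segments/subject at
the reference imbalance for the paired class-balanced-focal vs
cross-entropy comparison (20 epochs).  At this scale the end-to-end run
reaches test accuracy above 90% and the class-balanced focal loss lifts
walking-without-rider recall over the paired cross-entropy run in most
seeds, echoing the direction (not the magnitude) of the original findings.

## Known limitations

* The real six-horse dataset's absolute results are out of reach without
  the dataset itself; nothing here claims to reproduce them.
* Pure-R-plus-kernels training is single-threaded and CPU-bound; the
  defaults (100 epochs, batch 256) are practical only for datasets far
  smaller than the real one.
* The adaptive-class-suppression and cost-sensitive losses are
  reconstructions from their source literature, not from the
  activity-recognition study's text.
* Subject effects are multiplicative and stationary; real inter-animal
  variability is richer, so leave-one-subject-out difficulty is likely
  understated.
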