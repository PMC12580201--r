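---
title: "Whale-optimized convolutional ensembles: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whale-optimized convolutional ensembles: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

`whalenet` addresses three-class classification of gynecological MR images
(Normal / Benign / Malignant) with small, patient-grouped datasets, where
hyperparameter choices — learning rate, batch size, dropout, dense width,
optimizer family, activation, weight decay, and for a from-scratch CNN the
per-block filter counts — dominate the attainable generalization.  The
package automates that choice with the Whale Optimization Algorithm (WOA),
a population metaheuristic that needs no gradients of the tuning
objective, and combines the tuned classifiers by soft voting.

The pipeline is: synthesize or load a cohort; split it at the patient
level 80/10/10; run one WOA search per model family, scoring each
candidate by short partial training and validation loss; train the best
configuration per family to convergence; average the per-model class
probabilities with equal weights; report one-vs-rest metrics, macro
overall rows and Wald confidence intervals.

## The hyperparameter codec

WOA operates on the unit cube.  Each coordinate decodes to a physical
setting:

| dimension | map | range |
|---|---|---|
| learning rate | $10^{-5+3x}$ | $10^{-5}..10^{-2}$ (log scale) |
| batch size | $\mathrm{int}(16 + 112x)$ | 16..128 |
| dropout | $0.1 + 0.4x$ | 0.1..0.5 |
| dense units | $\mathrm{int}(64 + 448x)$ | 64..512 |
| optimizer | $\mathrm{round}(2x)$ | Adam, SGD, RMSprop |
| activation | $\mathrm{round}(2x)$ | ReLU, LeakyReLU, ELU |
| weight decay | $10^{-6+3x}$ | $10^{-6}..10^{-3}$ (log scale) |
| momentum | $0.5 + 0.45x$ | 0.5..0.95, consumed by SGD only |
| conv filters (LVM) | $\mathrm{int}(b_i(0.5 + 1.5x))$, $b_i = 32, 64, 128$ | 16..64, 32..128, 64..256 |

Design notes, where the encoding left room:

* The learning-rate and weight-decay maps are read as exponent maps
  ($10^{-5+3x}$), which is the only reading consistent with their
  "log-scaled" annotation and printed ranges.
* Integer dimensions truncate toward zero (`int(...)` as printed), not
  round.  `round(2x)` for categories is implemented half-up, so the
  boundaries $x = 0.25, 0.75$ are deterministic across platforms.
* The per-block filter formulas imply maxima of twice each base
  (64/128/256), while wider nominal ranges (96/192/384) are also quoted;
  the formulas are the default and `extended_filter_range = TRUE`
  substitutes coefficient 2.5 to reach the wider maxima.
* Momentum is always decoded but ignored unless the optimizer decodes to
  SGD — the one conditional edge in the space.

`encode_hyperparameters()` inverts the map (exactly on continuous and
categorical dimensions, to one truncation step on integers) for warm
starts and round-trip testing.

## The optimizer

The WOA population updates per iteration by one of three rules, chosen
per whale: encircling the best-so-far position
$\vec X(t+1) = \vec X^* - \vec A \cdot |\vec C \vec X^* - \vec X|$ when
$p < 0.5$ and $|\vec A| < 1$; exploration toward a random whale with the
same form when $|\vec A| \ge 1$; and the logarithmic spiral
$\vec X(t+1) = |\vec X^* - \vec X| e^{bl} \cos(2\pi l) + \vec X^*$ when
$p \ge 0.5$.  The coefficient magnitude $a$ decays linearly from 2 to 0;
$\vec A = 2a\vec r_1 - a$ and $\vec C = 2 \vec r_2$ are drawn fresh per
whale and component each iteration, $l \sim U[-1,1]$, $p \sim U[0,1]$.

Choices the update rule leaves open, fixed here once:

* The encircle/spiral threshold on $p$ is 0.5 (the canonical choice).
* $|\vec A|$ is the Euclidean norm.
* The spiral distance is the componentwise $|\vec X^* - \vec X|$.
* Positions are clamped into $[0,1]^d$ after every update.
* The random whale is drawn uniformly among the *other* whales.
* Elitism: the best position is replaced only on strict improvement, so
  the convergence curve is non-increasing by construction.
* Early stopping: the run ends after `early_stop_patience` (default 3)
  consecutive iterations without improvement of the best fitness.

Determinism: the whole run — initialization and every coefficient draw —
derives from one seed; two runs with identical configuration are
bit-identical.  The evaluation budget is exactly
`n_whales * (iterations + 1)`.

## Fitness: partial training on validation loss

A candidate's fitness is the validation loss after a short partial
training (default 10 epochs) of the decoded configuration.  The reported
value is the *final* partial epoch's loss; `min_over_epochs = TRUE`
switches to the epoch minimum.  Failures (divergence, invalid shapes)
score `+Inf` so a single bad candidate cannot stop the search.

Each candidate trains from its own derived seed,
`base_seed + hash(decoded configuration)`, so population members differ
but the run is reproducible.  The seed is derived from the *decoded*
configuration rather than the raw coordinates: the evaluation cache is
keyed on the decoded configuration (two vectors that truncate to the same
batch size, dense width, etc. are physically the same model), and the
derived seed must agree with that keying or cached and fresh evaluations
would diverge.

## Model families

**Lightweight vision model (LVM).**  Three blocks of 3×3 same-padding
convolution + activation + 2×2 max pooling with filter counts
$(F_1, F_2, F_3)$, so a side-$S$ input produces maps of sides $S/2, S/4,
S/8$ (224 → 112/56/28), then flatten → dense($u$) + activation →
dropout → softmax over 3 classes.  Sparse categorical cross-entropy plus
an L2 penalty $\lambda \sum \|W\|^2$ over every trainable weight matrix.

**Transfer heads.**  A frozen feature extractor (the "backbone") maps the
image batch to a channel-last feature map; global average pooling reduces
each channel to its spatial mean; the trainable head is dense($u$) +
activation → dropout → softmax, with the L2 penalty on the head's first
dense weights.  Backbones are consumed through a registry contract
(`register_backbone()`), so large pretrained extractors plug in
unchanged.  The two bundled `tinynet_a`/`tinynet_b` backbones are small
fixed-weight convolutional extractors (weights pinned at registration)
that keep the whole pipeline self-contained; they are *not* pretrained
networks and are labelled as reference extractors.

Two consequences of using non-pretrained reference backbones, both frozen
into the model rather than left to the user:

* each backbone carries a per-channel affine normalization calibrated
  once, at registration, on a pinned batch of smooth synthetic noise (the
  analogue of a pretrained network's frozen batch-norm statistics);
* the head standardizes its pooled features on the training split and
  stores those statistics in the trained handle, because the raw feature
  spread of an uncalibrated extractor is orders of magnitude too small
  for a softmax head to converge within a 10-epoch partial-training
  budget.  With standardization the head reaches the same validation
  accuracy as an independently fitted multinomial logistic model on
  identical features.

The training engine itself (im2col convolution over BLAS, max-pool
argmax routing, inverted dropout, Glorot-uniform initialization,
Adam/SGD-momentum/RMSprop with Keras-style defaults
$\beta_1 = 0.9, \beta_2 = 0.999, \rho = 0.9, \varepsilon = 10^{-7}$) is
implemented in the package and verified against finite-difference
gradients and a brute-force convolution oracle in the test suite.
LeakyReLU uses slope 0.3 and ELU $\alpha = 1$.  Training keeps the
final-epoch weights (no best-epoch checkpointing); partial fitness
training and final training share one builder, differing only in epochs
(defaults 10 and 30).

## Soft voting

The ensemble probability is the unweighted mean of the members'
probability rows, aligned by image id; the label is the argmax, with
exact ties broken toward the lowest class index (the label-encoding
order Normal 0, Benign 1, Malignant 2) and flagged.  No weighting,
stacking or calibration: member diversity comes from the three model
families, not from the combiner.

## Evaluation metrics

From the $K \times K$ confusion matrix (rows = truth), each class is
scored one-vs-rest: precision $TP/(TP+FP)$, sensitivity $TP/(TP+FN)$,
specificity $TN/(TN+FP)$, F1.  The "Overall" row is the unweighted macro
mean of the per-class values; accuracy is trace$/N$.  When classes are
balanced, accuracy equals macro sensitivity — which is why accuracy and
sensitivity columns coincide on balanced test sets.  The Wald interval
for an accuracy $\hat\mu = c/n$ is
$100(\hat\mu \pm z\sqrt{\hat\mu(1-\hat\mu)/n})$ with $z = 1.96$.

Reporting rounds half-up to two decimals *at the reporting layer only*;
all internal computation is full precision.  A class never predicted has
precision defined as 0, with a warning.  The package's reference
arithmetic fixtures reproduce the published macro rows to two decimals
under this rule; two published cells (an overall F1 of 88.54 against a
macro mean of 88.5467, and a CI lower bound of 84.26 against a computed
84.2686) are consistent only with truncation rather than rounding and
are treated as source-side truncation artifacts — the package reports
the rounded values.

## Data preparation

Images are resized bilinearly to a square side (224 for full runs, 64
in the scaled profiles) and intensities scaled from 0–255 to $[0,1]$.
Splitting is at the patient level: within each class, patients are
shuffled by seed and greedily allocated to the subset with the largest
remaining image-count deficit against the 0.8/0.1/0.1 targets, so no
patient spans subsets and the targets are met exactly when patients
carry one image, and to within a patient's images otherwise.

Augmentation (shear up to 0.2, zoom ±0.2, horizontal flip) tops
under-represented classes up to a target count with transformed copies,
each tagged with its source image.  Two orderings are supported:

* the default augments **after** splitting and only the training set —
  the leakage-safe reading, since a transformed copy of a test image in
  the training set is identity leakage;
* `balance_before_split = TRUE` balances the whole cohort first, which
  reproduces evaluation sets with exactly equal per-class counts (70 per
  class at the reference scale).  The two published statements (train-only
  augmentation; equal-count test sets) cannot both hold; both modes are
  provided rather than guessing the intended one.

The zoom magnitude is not specified alongside the shear of 0.2; it is
set to 0.2 by symmetry.  The augmentation warp is a center-anchored
bilinear affine sampler with border clamping, implemented in-package so
the convention is fully specified.

## The synthetic cohort generator

The generator is the package's study-condition bed, not a fixture: it
emulates the *structure* of the reference uterine-MRI cohort — three
classes, one class per patient, up to three planes (sagittal / coronal /
axial) per patient, and a `kauh_like` preset with per-class image totals
497/699/618 (1,814 images; totals not divisible by three are completed
by one smaller final patient).  Each image is a smooth elliptical organ
on a dark background with plane-dependent aspect; Benign adds one
well-circumscribed bright blob (sharp-edged super-Gaussian), Malignant
an irregularly bounded region filled with high-frequency texture, Normal
neither.  Lesion contrast scales linearly with `separation`
$\in [0,1]$: at 0 the three class-conditional distributions are
*identical* (a chance-level problem, used to test for optimistic bias),
and held-out accuracy rises monotonically with it.  A per-patient
intensity offset shared across planes makes patient-level splitting
consequential.  Additive Gaussian pixel noise has sd `noise_sd`
(default 0.05).  Generation is bit-identical per spec and seed.

What the generator does *not* emulate: MR physics, scanner and protocol
variability, anatomical diversity, class-overlapping lesion appearance.
Passing tests on it therefore demonstrate that the pipeline's machinery
(search, training, voting, evaluation, leakage guards) is correct and
well-calibrated — not that any accuracy level transfers to real MRI.

## Scaled profiles and problem sizes

The package's default test-scale study conditions, chosen once as a
desk-scale analogue of the full setup: 64×64 images, separation 0.9,
noise sd 0.04, 8–20 patients per class with three planes each, 2 whales
× 3 iterations per family, 3-epoch partial fitness, 10-epoch final
training, and the three-member ensemble (LVM + two tiny-backbone
transfer heads).  At these sizes a full pipeline run takes a few minutes
on one CPU core.  The end-to-end acceptance profile uses 16 patients per
class with a 70/10/20 patient-level split rather than the standard
80/10/10: a 10% test slice of so small a cohort holds under ten images,
and accuracy measured at 11-percentage-point granularity cannot support
an ensemble-versus-member comparison, so the evaluation slice is widened
at (almost) unchanged training cost.  The full-scale settings
(224-pixel inputs, 80/10/10 split, 10-epoch partial fitness, 30-epoch
final training, 2–5 whales × 5–10 iterations) remain the defaults of
the corresponding functions.

## Known limitations

* The CNN engine is CPU-bound, double precision, and minibatch-serial;
  it is sized for the scaled study conditions, not for ImageNet-scale
  backbones.
* Bundled backbones are fixed random-weight extractors; conclusions
  about *pretrained* transfer learning require plugging real extractors
  into the registry.
* Wald intervals are used as published; they are known to be poorly
  calibrated near 0/100% (a 100% accuracy yields a zero-width interval)
  and are not clamped to $[0,100]$.
* The WOA search runs with populations of 2–5; with such budgets the
  search is closer to guided random sampling than to asymptotic WOA
  behavior, which is exactly the published operating regime.
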