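---
title: "Multimodal tongue diagnosis: model, losses, and synthetic benchmark"
author: "tonguenet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal tongue diagnosis: model, losses, and synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tonguenet)
```

## The problem

Tongue inspection in traditional Chinese medicine (TCM) reads disease
*nature* (ten syndrome categories: cold, Qi deficiency, Qi stagnation, heat,
dampness, phlegm, blood deficiency, blood stasis, Yang deficiency, Yin
deficiency) and disease *location* (nine organ/region categories: intestine,
lung, liver, spleen, kidney, stomach, heart, others, healthy) from the
colour, coating and regional texture of the tongue. Clinically, a tongue
photograph comes with a structured expert description (body colour, coating,
teeth marks, cracks, regional signs). Both tasks are multi-label: a patient
can present several syndromes at once.

`tonguenet` implements a multimodal classifier over such image/text pairs,
an evaluation suite, three-annotator consensus curation utilities, and a
fully seeded synthetic data generator so the entire pipeline is testable
end-to-end without access to clinical data.

## Model

### Image encoder (hierarchical aggregation)

A 1x1 convolution (`stemProject`) lifts the RGB image into a hidden channel
space, giving level `Z0`. A chain of grouped 3x3 convolutions with GELU
(`hierarchicalEncode`) produces levels `Z1..ZN` with growing receptive
fields; the growth follows the exact recursion

$$ l(N) = l(N-1) + (k(N)-1)\prod_{i=1}^{N-1} s(i), $$

implemented in `receptiveField()` and verified in the tests against a
brute-force gradient-support oracle. Global average pooling of `ZN`,
broadcast over the grid (`globalContext`), forms the global-context level
`Z(N+1)`. A gate network (1x1 convolution over the channel-concatenated
levels, softmax across the level axis) assigns each pixel a convex weight
over levels `1..N+1`, and the encoder output is the gated sum
$\sum_l G_l \odot Z_l$ (`gatedAggregate`). Levels are aggregated on the grid
of `Z1`, the finest level entering the sum; coarser levels are bilinearly
upsampled.

The aggregated map is mean-pooled onto a fixed 4x4 grid, flattened, and
linearly projected to the embedding $Z_t \in \mathbb{R}^d$. The coarse grid
(rather than one global average) was chosen because tongue-region topography
(tip/sides/centre/root) carries the location signal; a global pooling is
translation invariant and would erase exactly the information the location
task needs.

Design choices the architecture leaves open and how they were fixed:
GELU after every grouped convolution; softmax normalization of the gates
(so the aggregation is a convex combination per pixel); gate network as a
1x1 convolution. Defaults: 4 levels, 64 hidden channels, 4 groups, d = 128.

### Text encoder

The text modality is a structured record over a fixed schema of categorical
sign attributes (`textSchema()`), one per observable sign, each with an
explicit `UNK` level; records are index-encoded (`vectorizeText`), embedded
per attribute, concatenated, and passed through a two-layer GELU perceptron
with dropout to a d-dimensional embedding $Z_s$ (`encodeText`). Treating
the text as attributes rather than prose matches how such datasets are
annotated; a free-text field can be folded in by mapping recognized tokens
onto schema values upstream.

### Dual-space representation

Both embeddings live in Euclidean space and, through the origin exponential
map

$$ \exp_0(v) = \tanh(\sqrt{c}\,\lVert v\rVert)\, \frac{v}{\sqrt{c}\,\lVert v\rVert}, $$

on the Poincare ball of curvature $-c$ (`expMapOrigin`, `clipToBall`,
default $c = 1$, clipping margin $10^{-5}$). The Euclidean "distance" is
deliberately the *squared* norm $D_{es}(x,y)=\lVert x-y\rVert_2^2$; the ball
distance is the standard

$$ D_{hs}^c(x,y) = \frac{1}{\sqrt{c}}\,\mathrm{arccosh}\Big(1 +
   \frac{2c\lVert x-y\rVert^2}{(1-c\lVert x\rVert^2)(1-c\lVert y\rVert^2)}\Big). $$

A sign variant of this formula in circulation places minus signs inside the
arccosh argument, which can push the argument below 1 where arccosh is
undefined; this package uses the standard form above, whose argument is
always $\ge 1$ (floored at 1 against rounding). The hyperbolic images feed
the loss terms only; the fusion path is purely Euclidean.

### Fusion, three subspaces, multi-scale attention

The modality embeddings are layer-normalized per sample (so neither modality
dominates by scale), concatenated, and mapped by an affine layer + GELU to
the fused feature $F$ (`bridgeFeatures`). Three affine maps give
complementary subspace views $F_1, F_2, F_3$ (`projectSubspaces`). Each view
is reshaped to a grouped spatial tile (default 8 channels as 4 groups on a
4x4 tile) so the multi-scale attention's height/width/global poolings

$$ z^H_c(h) = \tfrac1W \sum_i x_c(h,i), \quad
   z^W_c(w) = \tfrac1H \sum_j x_c(j,w), \quad
   z_c = \tfrac1{HW}\sum_{j,i} x_c(j,i) $$

are well defined (`emaPoolHeight`/`Width`/`Global`). The attention
(`emaAttention`) runs two branches per channel group: a shared 1x1 transform
of the concatenated `zH|zW` whose sigmoid gates modulate the map, and a 3x3
convolution branch; each branch's softmaxed global pooling is then
matrix-multiplied against the other branch's spatial features, the summed
interaction map passes through a learned single-channel 1x1 projection and a
sigmoid, and the resulting gate reweights the input. The final projection is
what makes the all-zero-parameter case collapse exactly to a 0.5 gate
(output = input/2), a property pinned in the tests. The three reweighted
views are summed and layer-normalized (`recombineSubspaces`).

### Kolmogorov-Arnold classifier heads

Each task has a two-layer KAN head: every edge carries a learnable
univariate function

$$ \phi(x) = w_{base}\,\mathrm{silu}(x) + \sum_m c_m B_m(x), $$

with cubic B-splines on 8 uniform intervals of $[-2, 2]$ (via
`splines::splineDesign`; linear continuation outside the grid), and node
outputs are plain sums $x_{l+1,j} = \sum_i \phi_{l,j,i}(x_{l,i})$
(`kanLayerForward`, `kanForward`). The classifier input is layer-normalized,
so activations match the spline support. The final layer is initialized so
that the head outputs each label's empirical prior logit before training
(the B-spline basis sums to one, so constant coefficients realize a bias);
the silu path stays mildly active so gradients reach the trunk. Pathology
and location heads share the fused trunk.

## Losses

With per-sample distances $d_{es} = D_{es}(Z_t, Z_s)$ and
$d_{hs} = D_{hs}^c(\exp_0 Z_t, \exp_0 Z_s)$ stacked over the batch:

* **Consistency** (`consistencyLoss`): $1 - \cos(d_{es}, d_{hs})$, zero iff
  the two batch distance profiles are positively proportional. The
  printed-norm variant with squared norms in the denominator is available
  via `consistency_denominator = "squared"`; it is not scale invariant and
  is kept for fidelity experiments only.
* **Cross-entropy** (`ceLoss`): mean binary cross-entropy over labels,
  probabilities clipped to $[10^{-7}, 1-10^{-7}]$.
* **Complementarity** (`complementarityLoss`): mean ball distance between
  the exp-mapped prediction vector and the exp-mapped binary target.
* **Total** (`totalLoss`): $w_{ce} L_{ce} + w_{consis} L_{consis} +
  w_{compl} L_{compl}$; defaults $1, 0.5, 0.5$. Setting
  $w_{consis} = w_{compl} = 0$ (or the ablation flags) reproduces a plain
  multi-label BCE trainer exactly, and the training-trace identity is
  asserted in the tests.

A practical note from this implementation: the complementarity gradient is
dominated by the norm mismatch between the interior prediction point and the
near-boundary target point, and its magnitude at initialization is several
times the BCE gradient's. At the small problem sizes this package runs (see
below), enabling it slows convergence rather than helping; the effect is
measured, not assumed, by the ablation experiment
(`runAblationGrid`). Whether it becomes beneficial at much larger training
scales is not something desk-scale runs can decide; see "Known
limitations".

## Training

`trainModel` runs minibatch Adam under the conventional hyperparameters
(learning rate 0.001, batch 16, 300 epochs, step-decay x0.1 every 100
epochs, He initialization, dropout 0.5 in the text encoder and fusion
trunk), with global gradient clipping (norm 5) and full seeding: identical
configuration and data give bitwise-identical runs. Non-finite losses or
runaway parameters abort with a diagnostic naming the component. Everything
runs on one CPU: the network is backed by a small reverse-mode autodiff
engine written for this package (convolutions as cached index gathers plus
matrix products), and every composite gradient is validated against central
finite differences in the test suite.

## Synthetic data generator

`buildDataset(generatorConfig(...))` emulates the structure of an
expert-annotated tongue dataset:

* **Labels**: independent Bernoulli draws per label (defaults: pathology
  prevalence 0.30; location 0.25 with healthy 0.15); `healthy = 1` forces
  all pathology bits to zero.
* **Images**: an elliptical tongue body on a dark background; each label
  shifts colour/coating/texture in its own region-channel signature (heat
  reddens the body, dampness brightens a central coating patch, heart
  textures the tip, kidney darkens the root, ...). `effect_size` scales the
  shift (0.08 per unit on the [0,1] intensity scale, capped at 0.4);
  Gaussian pixel noise sd 0.05. Deterministic given (labels, seed).
* **Text**: each sign attribute takes its label-implied value with
  probability `cross_modal_agreement`, otherwise a different level uniformly
  (so agreement 1 is deterministic and agreement 1/k is exactly
  label-independent).
* **Annotators**: three independent annotators flip each bit with
  `annotator_error_rate`; the unanimity probability has the closed form
  $((1-e)^3 + e^3)^L$ (`unanimityProbability`), which the consensus
  utilities are tested against.
* **Splits**: 0.70/0.15/0.15 by `round()`, mirroring a 3,370/722/722-style
  partition of 4,815 samples.
* **Joint-signal regime** (`joint_signal = TRUE`): every label becomes the
  XOR of one hidden per-sample image cue bit (a bright central patch) and a
  per-label hidden text cue bit, so each modality alone carries zero
  information about every label while the pair is decisive. This regime
  exists to probe whether the fusion path can exploit cross-modal
  interactions, not to look like a tongue.

What the generator does *not* emulate: photographic appearance, pose and
illumination variation, correlated label structure beyond the healthy rule,
annotator biases that are correlated across experts. Passing the synthetic
benchmarks therefore demonstrates that the implementation learns the
signals it was given, not that it would reach any particular accuracy on
clinical images.

## Problem sizes and the test-scale profile

Package defaults describe the full-scale model (64 hidden channels over 4
levels, 128-dimensional embeddings, 64-wide KAN hidden layer, 64x64
generator images, dropout 0.5). The test suite and the acceptance script use
`toyRunConfig()`: 16 hidden channels over 3 levels, 32-dimensional
embeddings, 32-wide KAN hidden layers, 16-32 pixel images, a few hundred
optimization steps (batch 16, or batch 32 with proportionally fewer steps
for the directional experiments), and dropout 0 — at a few hundred steps on
easy synthetic data dropout 0.5 only causes underfitting, so the test
profile disables it while the full-scale default keeps it. Experiments at this scale finish in
minutes on one CPU; their role is directional (orderings, identities,
calibration), not absolute performance.

## Numerical choices

* arccosh argument floored at exactly 1; ball clipping margin $10^{-5}$;
  the clipping rescale factor is treated as locally constant in the
  backward pass.
* BCE probability clip $10^{-7}$; cosine denominators stabilized by
  $10^{-24}$; layer normalization variance floor $10^{-5}$.
* B-spline evaluation outside $[-2,2]$ continues each basis function
  linearly (value and first derivative from the boundary).
* Softmax computed with per-row max subtraction; ties in the max are
  resolved to the first index so runs are bit-reproducible.
* Data-fraction subsampling ranks samples by a seeded priority within
  strata (any-positive-label), so the 25% subsample is contained in the
  50% subsample by construction.

## Known limitations

* The auxiliary losses do not improve desk-scale runs: across the regimes
  the package can afford (easy/undertrained, label-noise, small-sample
  overfitting), BCE-only training matches or beats the full loss, with the
  complementarity term the main drag (see the loss discussion above). The
  package reports what it measures; claims that these terms help at
  GPU-scale training on thousands of clinical images are outside what this
  benchmark can test.
* The generator's visual world is simple; models that exploit subtle
  photographic cues cannot be distinguished here.
* The autodiff engine favours clarity over speed; it is adequate for the
  bundled experiment sizes, not for full-scale training.
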