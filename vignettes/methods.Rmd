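---
title: "Methods: multi-layer feature fusion for few-shot image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-layer feature fusion for few-shot image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the model implemented by `protofuse`, the assumptions
and numerical conventions behind it, the choices made where the design was
genuinely open, and what the synthetic test fixtures do and do not
demonstrate.

## The episodic protocol

A labeled image collection is split by *class* into a source set
(meta-training) and a target set (meta-testing); the two class sets are
disjoint, so test-time categories are never seen during training. One
episode is an N-way, K-shot task: N classes are drawn uniformly without
replacement, and K support plus q query images are drawn per class, also
without replacement, making support and query sets disjoint by
construction. Defaults are N = 5, K ∈ {1, 5}, q = 5. Before sampling, every
image rotated by 90°, 180° and 270° is added under a new class label
(`augment_with_rotations()`), quadrupling the class inventory. Rotations
are exact array quarter-turns applied after the resize to 96 × 96, hence
lossless.

Two open points in this protocol were resolved as follows. Rotation
augmentation applies to both the source and the target collection by
default — the augmentation is described as acting on the whole dataset —
and `train()`/`evaluate()` expose `augment_rotations` so the
source-only variant is one flag away. Rotated variants of a class may
co-occur with their originals inside one test episode; nothing forbids it,
and forbidding it would bias episode composition toward easier tasks.

## The embedding function

The backbone is a four-block trunk; each block is a 64-filter 3 × 3
convolution, batch normalization, ReLU, and a 3 × 3 max pool with stride 3.
The convolutions use stride 1 and zero padding 1 ("same"), and the trunk
pools use floor division of the grid, giving map sizes 96 → 32 → 10 → 3 → 1.
Padding and stride are a design choice here (parameter counts do not depend
on them); this combination is the standard one and it makes the deepest map
1 × 1, so the deepest feature is global by construction.

After every block, the block output is tapped by a *global* max pool and
flattened to a 64-vector (`f1 … f4`). Global pooling is the only reading
under which every depth yields exactly 64 dimensions, which is what makes
the taps fusable. The fused embedding is the componentwise arithmetic mean
of the taps in the configured fusion subset; with subset `{4}` the model
degenerates to the plain global-feature baseline. Taps sit after ReLU, so
embeddings are componentwise nonnegative — a property the relative-entropy
head relies on.

Parameter accounting counts convolution weights and biases plus the
batch-norm scale and shift; batch-norm running statistics are not learnable
and are excluded. Cumulative branch counts are 1,920 / 38,976 / 76,032 /
113,088; the "total" row of `count_parameters(, "branch")` sums the four
branches (230,016) and therefore double-counts the shared trunk — it is
reported because it is the conventional per-branch ledger, while
`count_parameters(, "unique")` reports the deduplicated trunk size
(113,088, equal to the deepest branch).

### Batch normalization conventions

* Training mode normalizes with batch statistics over all spatial positions
  and images of the episode (support and query together form the batch);
  evaluation ("frozen") mode uses running statistics, making the forward
  pass deterministic. Population (biased) variance is used in both the
  normalization and the running average; `bn_eps = 1e-5`.
* Running statistics are updated with momentum 0.1.
* Because batch normalization subtracts the mean, the convolution bias
  preceding it shifts only that mean: in training mode it has exactly zero
  gradient, and the implementation folds it into the recorded mean rather
  than materializing a biased activation tensor. The bias remains a real
  (counted, serialized) parameter and enters frozen-mode inference through
  the running mean.
* Weight initialization is fan-in-scaled Gaussian (He), biases and shifts
  zero, scales one, seeded and reproducible.

## The metric head

Prototypes are support centroids. Query posteriors are a softmax over
negated divergences; exact posterior ties resolve to the lowest task-local
class index. Two divergences are implemented behind `divergence_config()`:

* **Squared Euclidean distance** on raw embeddings. The squared form is the
  one that makes the softmax a Bregman-consistent nearest-centroid rule in
  the prototypical-network family; an unsquared option exists for
  completeness but is not used in training.
* **Relative entropy** `KL(x‖y) = Σ_j x_j log(x_j/y_j)` between probability
  vectors obtained from the nonnegative embeddings. ε (default `1e-12`) is
  added to every component *before* sum-normalization: the ordering is not
  dictated by the formulation, and adding ε first is the variant that keeps
  the output an exact unit-sum distribution while still bounding every
  component away from zero. Posteriors are insensitive to ε across
  `[1e-14, 1e-10]` (a tested property). The log base defaults to e (nats),
  with base 2 (bits) exposed; the softmax consumes whichever scale is
  configured.
* KL is asymmetric and the formulation does not fix the argument order. The
  default is `KL(query ‖ prototype)` — weighting by the observation being
  classified, the usual convention when scoring an observation against
  references — and the reverse direction is available as
  `direction = "prototype_to_query"`. Neither is asserted to be canonical.

The episodic loss is the mean negative log-probability of the true class.
Probabilities are floored at `1e-30` before the log as an underflow guard;
with default smoothing the floor is never active.

## Training and evaluation

Training follows the reference schedule: Adam (β₁ = 0.9, β₂ = 0.999,
standard defaults since only the learning rate is prescribed), initial lr
`1e-3`, 100 epochs of 150 episodes at full budget. "Halved after 20
epochs" is read as periodic halving, `lr · 0.5^⌊e/20⌋`, the usual step
decay in episodic training; the literal single-halving reading is kept as
`lr_schedule = "single"`. No validation split or early stopping is used:
the final-epoch model is evaluated. Per-epoch history records the mean
episode loss and the training accuracy of the episode forward passes (i.e.
pre-update within each episode, averaged over the epoch).

Evaluation freezes the model, embeds every target image exactly once, and
then samples episodes in embedding space; this is mathematically identical
to embedding per episode (the frozen embedding of an image does not depend
on the episode) and makes thousand-episode evaluation cheap. Reports give
the mean episode accuracy with a normal-approximation 95% confidence
half-width (1.96 × SE over episodes); per-episode accuracies are retained.

All gradients are analytic and hand-derived (the convolution via
im2col/col2im adjoints, pooling via argmax scatter, batch-norm backward with
batch statistics, and the divergence heads including the normalization
chain); they are verified in the test suite both by finite differences at
the head level and by the loss-decrease property of a small gradient step.
Max-pooling makes the loss only piecewise smooth, so finite-difference
checks sit at exact agreement away from argmax switches.

## The synthetic fixture generator

`generate_collection()` emulates the regime of a small curated image
dataset: tens of visually distinct classes, ~15 images per class, moderate
within-class appearance variation. Each class is a procedural motif — one of
five shape families, crossed with eight hues and six stripe-grating
orientations (240 distinct classes; exceeding the capacity is an error that
states it). Stripe orientations are deliberately non-multiples of 90°, so
quarter-turn rotations of any class are genuinely new visual classes, which
is what rotation class augmentation assumes. Within-class variation is
translation (±5% of the frame), scale (±6%), stripe phase (≤0.12 cycle)
jitter plus clipped additive uniform noise (default amplitude 0.05); one
master seed spawns an independent stream per class, so generation is
bit-reproducible and adding classes never perturbs existing ones.

`class_separation` interpolates every class's rendered motif toward a
single shared reference motif: at 0 all classes are identically distributed
and any classifier is at chance; at 1 classes are maximally distinct. The
generator is calibrated so that at separation 1 and small noise a plain
nearest-prototype classifier on raw pixel vectors already exceeds 90%
5-way 1-shot accuracy — the jitter amplitudes above were chosen to meet
that contract (translation is the dominant nuisance for raw-pixel
matching) — while episode accuracy is monotone in the separation knob.
Both properties are tested by Monte-Carlo over ≥500 episodes.

Two caveats about what passing these tests shows. First, with a *fixed*
generated pool the dataset-conditional chance level of nearest-prototype
episodes deviates from 1/N by a finite-pool offset that no amount of
episode averaging removes; chance-level tests therefore use generous pools
(≥400 records) and allow an explicit ±0.01 beyond the 3σ episode band.
Second, the motifs are trivially separable compared to real photographs:
the fixtures validate the machinery (shapes, gradients, protocol,
reproducibility, monotonicity, null behavior), not field performance.
Published-scale accuracies on real insect imagery require the external
dataset and the full training budget (`scripts/full_benchmark.R`) and are
out of scope for the test suite.

## Problem sizes used by the test suite

The suite runs entirely on generated fixtures, sized for a single CPU:
training sanity uses 10 source/10 target classes × 10 images at full
separation with a reduced budget of 2 epochs × 20 episodes (5-way 5-shot),
evaluated over 500 frozen episodes; chance-level nulls use 16 classes × 25
images at zero separation over 500 episodes; reproducibility checks use
1 epoch × 3 episodes twice. These sizes are the package's own choice of a
minimal convincing demonstration for each property.

## Known limitations

* Only 3 × 3 convolutions are implemented (the architecture is fixed at
  that kernel); filters, depth, pool kernel and input size are
  configurable, but inputs must survive four floor-divided poolings
  (≥81 px for pool kernel 3).
* Training uses the squared-Euclidean or relative-entropy heads only;
  cosine/L1/Mahalanobis similarities are out of scope.
* Single-threaded CPU implementation; no GPU or distributed path.
* Batch-norm behavior with very small episodes (few images) is noisy, as in
  any batch-statistics regime; the episode itself is the batch.
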