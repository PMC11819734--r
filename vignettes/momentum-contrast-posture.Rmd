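---
title: "Momentum-contrast representation learning for equine posture imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Momentum-contrast representation learning for equine posture imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Horses express affective state largely through body posture — the carriage
of the neck, head and tail — rather than through the face alone.  equimoco
implements an end-to-end pipeline for studying that signal without labeled
data: footage of free-living horses is distilled into quality-controlled
crops, a small single-channel convolutional encoder is pretrained with
momentum contrast on edge-emphasised views of those crops, and the learned
representation is probed two ways — with a frozen-encoder emotion classifier
trained on a small labeled subset, and with unsupervised structure analysis
(t-SNE projections and silhouette-scored cluster counting) of the embedding
space.

The emotion taxonomy is the seven cross-mammalian primal affective systems
(Care, Seeking, Fear, Lust, Play, Rage, Grief) plus Pain, giving eight
classes and a 12.5% uniform-guess baseline.

## Retrieval: from video to crops

Footage is sampled at a low effective rate (default 0.1 frames per second,
i.e. every `round(source_fps / target_fps)`-th frame starting at frame 0;
redundant neighbouring frames carry almost no new information).  A pluggable
detector proposes bounding boxes per frame; the package ships a stub
detector for the synthetic fixtures (threshold + connected components, which
provably reproduces the generator's ground-truth boxes) and a
`make_detector()` adapter for an external object detector.  Detections pass
two filters:

* **resolution** — both sides at least `min_side` pixels (default 250);
* **intensity variability** — the standard deviation of the crop's
  \[0,1\]-scaled grayscale intensities must be below `sigma_threshold`
  (default 0.4).  For intensities bounded in \[0,1\] this statistic can
  never exceed 0.5, so the default is a mild cap.  The filter direction
  (accept-if-below) follows the printed inequality; both the direction and
  the threshold are configurable and every run report logs reject counts by
  reason so the choice is auditable.

Pixel intensities are scaled by the bit-depth maximum (255 for 8-bit) and
the statistic is computed on the grayscale channel; per-channel variants
were left out because the corpus is grayscale downstream anyway.

## Asymmetric augmentations

Contrastive training consumes two views of each image.  The query branch
applies: random resized crop (area fraction 0.66–1.0), grayscale, a fair
horizontal coin-flip, occasional Gaussian blur (p = 0.1, kernel 5, sigma
drawn from \[0.1, 2\]), a Sobel edge-magnitude filter, and normalisation.
The key branch is deliberately tamer — crop area 0.85–1.0, no flip, no blur
— giving the momentum encoder a more deterministic target.  Both branches
emit exactly one channel, which is what licenses the single-channel encoder.

Numerical choices worth recording:

* Sobel output is a single magnitude channel `sqrt(Gx^2 + Gy^2)` (not
  stacked gradients), computed with reflective borders and rescaled by the
  theoretical maximum response `4 * sqrt(2)` (each 3×3 kernel's response to
  \[0,1\] inputs is bounded by 4; a test enumerates all binary 3×3 patterns
  to confirm the bound).
* Grayscale conversion uses the standard luma weights (0.299, 0.587, 0.114).
* The crop's pixel dimensions are rounded *up* from the sampled area so the
  realised area fraction never falls below the drawn one, even on coarse
  grids.
* Normalisation constants default to the identity; the supported workflow
  fits corpus-level mean/sd on the pretraining split once
  (`estimate_normalization()`) and stores them in the run configuration.
  One-channel constants are used since views are single-channel.
* The aspect-ratio interval of the random resized crop is (3/4, 4/3).

## The encoder

A plain four-convolution CNN (1→32→64→128→256 channels, 3×3 kernels,
same-padding, ReLU), 2×2 max-pooling **after the second and fourth
convolutions**, flatten to `channels * (side/4)^2`, a 2048-unit hidden
layer with dropout 0.8, and a linear projection to the representation
dimension (64).  A reference description of this architecture applies
pooling only once yet flattens by `(side/4)^2`; the two-pooling placement is
the variant under which that flatten arithmetic is valid, so it is the one
implemented.  Input sizes 112 (the training default) and 224 are both
supported; any multiple of 4 works.

Embeddings are L2-normalised with an epsilon of 1e-12 added to the norm, so
the all-zero embeddings that heavy dropout can produce early in training
normalise to zero instead of NaN.

No deep-learning framework is available in this package's dependency
footprint, so the conv/pool/linear/batch-norm/dropout layers and their
backward passes are implemented directly (im2col plus BLAS matrix
multiplication).  Every backward pass is validated against central finite
differences in the test suite; the convolution forward pass is validated
against a direct-loop oracle.

## The contrastive objective

With unit-norm embeddings, cosine similarity is the dot product.  For one
positive pair the batch-form NT-Xent loss is

    l(i, j) = -log[ exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) ]

Training uses the momentum-contrast mechanism: a FIFO queue of up to K past
key embeddings supplies the negatives, and the per-query loss is the
InfoNCE form over {positive} ∪ queue.  The two formulations coincide when
the "batch" is `{q, k+} ∪ queue` — the package exposes both, trains with
the queue form, and the test suite verifies the identity numerically to
1e-10 on random instances.  Defaults are the published training values:
temperature 0.07, key momentum 0.999, queue capacity 65,536, batch size 32,
2000 epochs, SGD (lr 1e-4, momentum 0.9, weight decay 1e-4).

Mechanism details decided here:

* The key encoder starts as a copy of the query encoder and is updated as
  `key <- m*key + (1-m)*query` after every step.
* Keys are encoded in inference mode (no dropout): the momentum encoder's
  role is to provide stable targets, and dropout noise on targets only
  slows the probe metrics at small scale.  The query branch keeps dropout.
* Queue initialisation: `"random"` fills the queue with random unit vectors
  so the denominator is defined from step 1; `"empty"` grows the queue from
  real keys instead (first batch seeds it).  The desk-scale profile uses
  the grow mode so the first epoch's loss is measured against real
  negatives, making first-vs-final loss comparisons meaningful.
* The queue capacity default (65,536) exceeds a few-thousand-image corpus,
  so each image's stale keys recur as negatives; that is inherent to the
  mechanism at small corpus size and is visible as a nonzero loss floor.

## Downstream probe

The pretrained encoder is frozen (bit-identity is asserted before and after
head training) and a small head — 64→256→128→64→8 with batch
normalisation, ReLU and dropout 0.5/0.5/0.3 — is trained with
cross-entropy.  The dropout triple follows the reference implementation's
code; its prose description (0.5/0.3 only) conflicts and was not used.
Because the encoder is frozen, features are computed once per image with the
deterministic evaluation transform (full-frame resize → grayscale → Sobel →
normalise) and the head trains on cached features.  Batch normalisation
requires more than one sample, so minibatches of size 1 are skipped and a
minimum of 2 training samples is enforced.  Evaluation uses argmax with
ties broken toward the lowest class index; classes absent from a test set
are reported as `NA`, never as zero accuracy.  An internal 80/20 split of
the fine-tuning set (seeded) provides the validation accuracy curve.

## Embedding analysis

t-SNE (perplexity 30, fixed seed) maps 64-D embeddings to 2-D for display.
Cluster counting is done on the 64-D embeddings, not the projection — t-SNE
distorts densities, so a visual count from the 2-D map is weak evidence.
The estimator runs k-means (10 restarts, fixed seed) over a k range and
scores each clustering by mean silhouette width; the full score table is
returned so any claim about the number of clusters is auditable.  No target
cluster count is asserted anywhere: on real data the interesting
observation is whether the estimate exceeds the eight nominal classes, and
that is left to the analyst.

## Synthetic fixtures: what they emulate and what they do not

The real corpus (3,929 images, five wild breeds: Eriskay 711, Insh Konik
781, Pottoka 809, Skyros 796, Konik 832) is proprietary.  The fixture
generator emulates its statistical skeleton: grayscale images containing a
single dark silhouette on a light background whose latent class is encoded
purely in posture-like geometry.  Each of the eight classes owns a distinct
region of (neck angle, head drop, tail angle) space, separated by more than
the ±4° within-class jitter, so classes never overlap; bodies, legs and
overall scale vary slightly; pixel noise (default sd 0.02 in intensity
units) and optional pre-blurring add nuisance variation.  The intra-class
variability of the real corpus is not documented anywhere, so these noise
levels are a free choice, fixed in the configuration object.

A raw-pixel nearest-class-centroid oracle certifies learnability: the
default 8-class set scores ≥ 0.9 held-out accuracy at noise sd ≤ 0.05.
Passing tests on fixtures therefore demonstrates that the *mechanics* —
augmentation invariances, the contrastive objective, freezing, the
reporting — behave as specified on separable posture geometry.  They do not
demonstrate ethological validity, robustness to occlusion, background
clutter, multi-animal scenes, or the real corpus's accuracy numbers, none
of which the fixtures model.

The emotion-name ↔ geometry assignment is arbitrary but fixed:

| emotion | neck angle | head drop | tail angle |
|---------|-----------:|----------:|-----------:|
| Care    |  35 |  10 | -30 |
| Fear    |  75 |  -5 |  40 |
| Grief   | -10 |  55 | -70 |
| Lust    |  55 |   5 |  70 |
| Pain    | -30 |  70 | -10 |
| Play    |  65 | -35 |  10 |
| Rage    |  15 | -15 |  55 |
| Seeking |   5 |  35 |  -5 |

## The desk-scale study

`run_desk_study()` exercises the full pipeline at a problem size chosen to
finish in a few minutes on one CPU core: 8 classes × 32 fixtures at 32 px,
split 50/25/25 (stratified by breed) into pretraining / fine-tuning / test
partitions, an 8/16/32/32-channel encoder with a 128-unit hidden layer and
dropout 0.2, a 128-key queue grown from real keys, 40–50 pretraining
epochs, and a 150-epoch head.

Two desk-profile optimisation values differ from the full-scale defaults,
for a structural reason worth recording: at initialisation a deep ReLU
stack maps every input to almost the same direction (cosine similarities
≈ 0.998 even after input standardisation), so contrastive training must
first amplify tiny embedding differences.  The gradient that does this is
proportional to the deviation of each positive key from the embedding mean,
and escaping the near-collapsed region within a ~400-step budget needs
larger steps (SGD lr 0.05) and a faster-tracking key encoder (momentum
0.99) than the published full-scale values (1e-4 and 0.999), which have
hundreds of thousands of steps available.  With this profile the run
reproduces, at desk scale, the qualitative claims of the method: the
pretraining loss falls from the first to the last epoch, the latent-class
silhouette of the embeddings roughly doubles relative to the untrained
encoder, and the frozen-encoder probe beats the 12.5% baseline several-fold
(about 7× at seed 1).

## Known limitations

* Single-worker determinism only; no multi-device training, no shuffling
  batch-norm, no mixed precision.
* The queue stores stale keys of the corpus itself when K exceeds the
  corpus size, bounding the attainable loss from below.
* The pure-R layer stack is fast enough for desk-scale studies but not for
  the full 112-px, 65,536-key configuration; that configuration is
  expressible and validated structurally (parameter counts, flatten
  arithmetic) but not trained in the test suite.
* Overlapping detections are not deduplicated (no policy was specified for
  the original pipeline); multi-animal frames are supported by the detector
  interface but fixtures render one animal per frame.
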