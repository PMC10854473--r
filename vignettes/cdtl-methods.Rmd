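---
title: "Methods: entropy-based slice selection, class decomposition, and transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based slice selection, class decomposition, and transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtl)
```

# The problem and the overall procedure

Predicting conversion from mild cognitive impairment (MCI) to
Alzheimer's disease from a single structural MRI is a hard binary task:
stable (sMCI) and progressive (pMCI) brains look very similar at
baseline. The classification of Alzheimer's patients (AD) versus
cognitively normal controls (CN) is much easier, and the two tasks share
anatomy and feature structure. `cdtl` operationalizes that relationship
as a two-stage pipeline:

1. **Base stage.** From each subject's volume, keep the 20 axial slices
   with the highest co-occurrence entropy. Fine-tune a feature extractor
   on the AD/CN labels, reduce the extracted features with PCA, scale
   them, split each class into k = 2 k-means subclasses, relabel every
   slice with its subclass, and train a classifier on the subclass
   labels. Predictions are reassembled to parent classes.
2. **Target stage.** Keep the 30 middle slices per subject. Freeze every
   body parameter of the base classifier, replace its head with a fresh
   binary head, and retrain only the head on sMCI/pMCI labels.

Evaluation always groups by subject: a subject's slices never straddle a
train/test boundary, because slices of one subject are strongly
correlated and would otherwise leak identity.

# Slice selection

For a quantized image with gray levels $0,\dots,L-1$, the gray-level
co-occurrence matrix at distance $D$ and direction $\theta$ is the
normalized count $p(i,j)$ of pixel pairs $(x, x+\Delta_{D,\theta})$ with
levels $(i, j)$. Its Shannon entropy
$H = -\sum_{i,j} p(i,j)\,\log p(i,j)$ (with $0 \log 0 := 0$) is low for
flat or blocky slices and high for texture-rich ones; across a brain
volume it peaks in the central slices, which carry the most anatomy.

Choices the co-occurrence literature leaves open, fixed here as
defaults:

* $D = 1$, $\theta = 0^\circ$, 64 gray levels, symmetric counting,
  natural logarithm (entropy in nats). A `"mean4"` direction averages
  the four standard angles. 64 levels keeps the matrices small and
  desk-scale runtimes low.
* Quantization is per-slice min–max into $L$ uniform bins; a constant
  slice maps to a single bin and gets entropy exactly 0 — never an
  error.
* Ranking ties are broken by ascending slice index, making selection
  deterministic.
* Entropy is computed on the quantized image, not raw float
  intensities, so rankings are invariant to affine intensity changes.

`select_top_entropy()` keeps the top-$n$ slices per subject (default
20); `select_middle()` keeps a centered window of $n$ slices (default
30) starting at $\lfloor (N-n)/2 \rfloor$ — for $N = 189$ axial slices
and $n = 30$ that is indices 79..108. Both clamp gracefully when fewer
slices exist.

# Class decomposition

Within each parent class, k-means (seeded, 10 restarts, 300 iterations
max) partitions the reduced feature vectors into $k$ subclasses
(default $k = 2$), and samples are relabeled `"<parent>#<cluster>"`.
Cluster indices are ordered by the first centroid coordinate so the
labeling does not depend on k-means' internal permutation. A class too
small to support its $k$ falls back to $k = 1$ with a warning (or an
error when the fallback is disabled).

The feature space matters. The reduction is PCA fitted on training rows
only (fraction-valued `n_components` keeps the smallest count reaching
that explained-variance share, default 95%), and the retained component
scores are standardized *after* the projection. Texture statistics enter
PCA in their natural units: standardizing each raw feature first would
inflate near-constant statistics into unit-variance noise axes that
drown the informative directions — we observed exactly this failure mode
during development, with subcluster recovery collapsing once block
standard deviations and entropies were pre-standardized. The network
backbone standardizes its own inputs internally, where optimization
(not geometry) is the concern.

Silhouette diagnostics (`silhouette_by_class()`) are computed in the
reduced, scaled space — the space the clustering saw — and a parent with
a single nonempty subclass is reported as `NA` (undefined), not as a
number.

Reassembly supports two modes. `argmax_map` (default, the simplest
faithful reading of "reassemble the subclasses") takes the parent of the
highest-scoring subclass; `prob_sum` sums subclass probabilities within
each parent and takes the argmax parent. They can disagree: with
subclass scores (A#0, A#1, B#0, B#1) = (0.35, 0.05, 0.30, 0.30),
`argmax_map` answers A while `prob_sum` answers B (0.60 > 0.40). Both
are exposed so the choice is auditable.

# Backbones and the transfer contract

Feature extractors and classifiers are pluggable behind
`backbone_spec()`. The package ships two desk-scale reference
implementations:

* `reference_cnn` — fixed, seeded random 3×3 convolution filters with
  ReLU and mean pooling feeding a trainable dense tail and a softmax
  head, trained with a hand-rolled Adam (seeded batching, fully
  deterministic). `n_trainable_tail_layers` controls how many dense
  layers ahead of the head train — the single knob standing in for
  "adopting the top layers" of a large pretrained network. The
  convolutional front never trains.
* `deterministic_texture` — a non-neural extractor: 4×4 grid block means
  and SDs, global moments, GLCM entropies at the four standard angles,
  and mean absolute gradients (40 features). It has no training state at
  all, which makes every downstream computation bit-reproducible — the
  backbone used wherever tests assert exact determinism.

Large ImageNet-pretrained architectures can be adapted behind the same
contract; nothing in the decomposition or transfer machinery looks
inside a backbone.

The transfer protocol is enforced, not assumed: `body_digest()` hashes
every body parameter (filters, normalization, all dense layers but the
last). `freeze_and_replace_head()` records the digest, and
`retrain_head()` — which trains only the new head, on body activations
precomputed once — re-derives the digest afterwards and fails loudly on
any mismatch. The training defaults mirror the published regime (200
epochs, batch 50, Adam, learning rate $10^{-4}$); tests and examples use
far fewer epochs with a larger learning rate, which the small reference
networks need to converge at desk scale.

# Cross-validation, aggregation, imbalance

`make_subject_folds()` deals each class's subjects (seeded shuffle)
round-robin into folds: every subject is held out exactly once and
per-class fold sizes differ by at most one. `run_cv()` trains each
fold's model on the remaining subjects and evaluates held-out subjects
at both slice and subject level; each fitted component records the
subjects it saw, and the runner verifies that record against the fold's
training set — a leakage guard that runs on every fold of every CV.
Both a fixed 90/10 subject split (`holdout_split()`) and k-fold CV
(default 10 folds) are supported.

Slice-to-subject aggregation is not standardized anywhere, so both
rules are implemented: `slice_majority` (default; modal slice
prediction, ties broken by the higher mean score) and `mean_score`
(average the score vectors, then argmax).

Class imbalance (e.g. 321 stable vs 146 progressive subjects) is
handled by random oversampling with replacement until counts are equal —
duplicating *whole subjects*, never individual slices, so the grouping
guarantee survives; duplicated subjects get a `.dupK` suffix to keep
keys unique. With `by_stratum = TRUE` each stratum (e.g. each sex)
balances independently; a single-class stratum is warned about and left
unchanged. The pipeline applies oversampling to training folds only.

Metrics come with an explicit undefined convention: sensitivity,
specificity, precision, or F1 with a zero denominator are `NA`, never a
silent 0 or 1. This matters for small single-class test strata, where
accuracy can be 1 while F1 is meaningless. AUC uses the rank
(Mann–Whitney) formulation with ties counted 0.5; its confidence
interval is a seeded stratified percentile bootstrap (default 1000
resamples, 95%) — a distribution-free, reproducible choice.

# The synthetic-data generator

The generator exists so that every pipeline guarantee has a test that
*could fail* if the corresponding mechanism broke.

**Phantoms** (`make_phantom()`): slices in a centered band (default
fraction 1/3 of a 64×64×60 volume) are fine-grained white-noise texture
— a near-uniform co-occurrence distribution, hence high entropy — while
outer slices are blocky smoothed noise whose equal-valued neighbors
concentrate co-occurrence mass near the diagonal (low entropy).
Informativeness therefore *coincides with* GLCM entropy by
construction; with zero background noise the outer slices are exactly
constant and score entropy 0. The planted band is returned as ground
truth.

**Classification tasks** (`make_classification_task()`): two orthogonal
unit-SD spatial patterns carry the signal. Class identity sets the
amplitude of one pattern (centers ±1 for two classes); subcluster
identity sets the amplitude of the other, with centers
`subcluster_separation` within-cluster SDs apart (within-cluster SD
fixed at 0.15). A subject draws its amplitudes once; its slices share
them plus independent pixel noise (SD 0.05), emulating the
within-subject correlation that makes subject-grouped CV necessary.
`class_overlap` (default 0.25) is the subject-level SD of the class
statistic: at 0 a hard threshold separates the classes exactly.
Imbalance and stratum proportions are honored exactly (largest-remainder
apportionment), and hidden subcluster labels ride along for
adjusted-Rand-index scoring.

`class_axis_coupling` (default 0) deserves a note. With coupling 0 the
classes are linearly separable and decomposition cannot be expected to
improve accuracy — a plain classifier already represents the boundary.
At coupling 1 each subcluster's class-statistic center is mirrored
across classes (an XOR-like interleaving), the boundary becomes
irregular, and subclass training is the natural remedy: this is the
regime in which the decomposition-benefit property is asserted.

**Transfer pairs** (`make_transfer_pair()`): the target task reuses the
base task's template family with class centers contracted by
`target_shift` toward zero — statistically identical at 0, progressively
harder toward 1, labels suffixed `_t`. Transfer from the base task is
beneficial by construction because the informative directions coincide.

What the generator does *not* emulate: brain anatomy, atrophy patterns,
scanner effects, registration error, or site heterogeneity. Passing
tests demonstrate that the mechanisms (entropy ranking, subclass
recovery, freeze contract, grouped CV, reassembly arithmetic) are
implemented correctly — not that any particular accuracy will be reached
on clinical data.

# Numerical choices and degenerate inputs

* GLCM probability matrices must sum to 1 within $10^{-9}$; an image
  smaller than the requested offset is a degenerate-input error.
* Constant images quantize to a single bin (entropy 0) rather than
  erroring; zero-variance PCA scores get unit scale instead of dividing
  by zero.
* k-means label permutation is removed by sorting clusters on the first
  centroid coordinate; all stochastic steps (k-means restarts, network
  initialization and batching, bootstraps, fold shuffles, oversampling
  draws) are seeded, and per-fold seeds derive from the master seed.
* Argmax ties anywhere resolve to the first column, and subject-vote
  ties to the label with the higher mean score — documented, tested
  rules rather than platform accidents.

# Problem sizes

Examples, tests, and the acceptance script run on deliberately small
instances — typically 10–16 subjects per class, 3–8 slices per subject,
16×16 to 64×64 pixel images, tens of epochs — chosen so the full suite
executes in a few minutes on one CPU while still exercising every code
path at the generator's default study conditions (e.g. subcluster
separation 8, 12 subjects per class for recovery checks). The training
defaults in `train_config()` remain the published large-scale regime.

# Known limitations

* The reference backbones are deliberately small; they demonstrate the
  protocol, not state-of-the-art image features. Plugging in a modern
  pretrained network is expected for clinical-scale work.
* Stage-2 decomposition of the target task is available behind
  `decompose_target` but off by default: the faithful reading of the
  transfer step is a plain binary head.
* Only random duplication oversampling is provided (no synthetic-minority
  interpolation), matching the evaluated procedure.
* Multi-class (>2 parent) problems pass through the decomposition
  machinery structurally but the pipeline stages validate binary tasks,
  which is what the application defines.
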