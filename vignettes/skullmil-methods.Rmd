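---
title: "Sex estimation from skull volumes with gated attention MIL: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex estimation from skull volumes with gated attention MIL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skullmil)
```

## The problem

Forensic sex estimation from the skull rests on sexually dimorphic
morphology — most prominently the mandible (square in males, rounded in
females) and the robustness of cranial ridges. `skullmil` implements a
reproducible pipeline that learns this discrimination from binarized 3D
skull volumes (postmortem CT, bone isolated at a Hounsfield-unit threshold)
and, crucially, *shows its evidence*: the model weighs sub-volumes of the
skull and the weights can be rendered as a heatmap over the anatomy.

## The model

A whole skull volume is treated as a *bag* of K patches obtained by tiling
the volume with a non-overlapping cubic grid (27 patches of $100^3$ for a
$300^3$ volume; 27 patches of $20^3$ at the desk scale of $60^3$ used
throughout the tests). Multiple-instance learning (MIL) classifies the bag
without patch-level labels.

Each patch is embedded by a small 3D CNN encoder into $h_k \in
\mathbb{R}^M$. The bag representation is the attention-weighted sum

$$z = \sum_{k=1}^{K} a_k h_k,$$

with gated attention weights

$$a_k = \frac{\exp\{w^\top(\tanh(V h_k^\top) \odot \sigma(U h_k^\top))\}}
            {\sum_{j=1}^{K}\exp\{w^\top(\tanh(V h_j^\top) \odot \sigma(U h_j^\top))\}},$$

where $w \in \mathbb{R}^{L}$, $V, U \in \mathbb{R}^{L \times M}$ are
trainable, $\odot$ is the elementwise product and $\sigma$ the logistic
function. The ungated variant drops the $\sigma(Uh^\top)$ factor. We use
$L = 128$ and a single attention branch, following the original
attention-MIL design; the gated variant is the default. The pooled vector
$z$ is classified by a single affine layer with a logistic link; female is
the positive class and the decision threshold is 0.5.

The bag-level loss is the negative log-likelihood
$-(Y\log p + (1-Y)\log(1-p))$ with the prediction clipped to
$[10^{-7}, 1-10^{-7}]$. (Some write-ups display the positive
log-likelihood under the name "negative log likelihood loss"; the
implementation minimizes the properly negated expression, since minimizing
the positive log-likelihood would maximize error.)

### Optimization

Training uses AdamW with learning rate $10^{-4}$, decoupled weight decay
$5\times10^{-4}$, dropout 0.3, one bag per optimization step, at most 1000
epochs, and early stopping: training halts when the running minimum of the
validation loss has not been improved for 50 consecutive epochs, and the
returned model is the one from the best-validation epoch. Dropout is
applied to the patch embeddings and to the pooled vector entering the
classification head; this placement is a design choice of this package (it
is the narrowest part of the network, where dropout acts as bag-level
regularization). A single seed governs initialization, shuffling, dropout
and augmentation, so a fit is bit-reproducible on one machine.

"Patience 50" is read as: stop at the first epoch $t$ with $t - t^\ast \ge
50$, where $t^\ast$ is the epoch of the current strict minimum. A constant
validation loss therefore stops training at epoch 51.

### The reference encoder

The encoder contract is pluggable: anything mapping a patch to a length-M
vector works, and a large dense-convolutional encoder can be configured for
$100^3$ patches. The desk-scale reference encoder is deliberately small so
the full pipeline trains in minutes on one CPU core:

* block 1: valid convolution, kernel = stride (a "patchify" convolution,
  kernel 4 for side-20 patches), 8 channels, ReLU;
* block 2: valid convolution, kernel 2, stride 1, 8 channels, ReLU,
  max-pool 2;
* flatten, dense projection to $M = 32$, ReLU.

Making the first kernel equal its stride is a throughput choice: the
im2col of a non-overlapping convolution is a pure reshape, which matters
when every training step runs through R matrix algebra rather than a
compiled tensor library. The layers are hand-implemented (im2col matrix
products with manual backpropagation) because no deep-learning framework
is part of this package's dependency set; gradients are verified against
brute-force convolution oracles and finite differences in the test suite.

With binary inputs and zero-initialized biases, ReLU pre-activations can
sit exactly at a kink and non-overlapping max-pool blocks can tie at zero;
ties share the subgradient equally. Both events vanish after the first
optimizer step and do not affect training.

## Volume preprocessing

Inputs are standardized in a fixed order: resample to isotropic spacing
(1 mm default; linear interpolation for HU volumes, nearest-neighbour for
binary masks so they stay binary), reorient to a canonical axis convention,
centre crop/zero-pad to a cube (default $300^3$), then binarize at
$\ge 500$ HU (bone on bone-algorithm reconstructions). The canonical
convention is fixed to **RAS as direction of increase** (x grows to the
patient's right, y to anterior, z to superior); phrases like "right to
left" are ambiguous between direction-of-travel and direction-of-increase,
so the package picks the direction-of-increase reading and writes it into
every output header. Whether binarization happens before or after padding
is immaterial (the pad value 0 is below any bone threshold); the order
above is simply fixed and documented. Odd crop/pad differences put the
extra voxel on the trailing side of the axis.

## Age balancing

Skull shape changes with age, so an age imbalance between the sexes would
let the model learn age, not sex. The cohort builder fits a logistic
regression of the male label on age (age is the only covariate being
adjusted), then greedily pairs each minority-sex subject with the nearest
unmatched majority-sex subject on the propensity scale, visiting minority
subjects in seeded random order and refusing pairs further apart than 0.2
standard deviations of the pooled propensity scores. The caliper is applied
on the probability scale (not the logit), matching the convention of the
matching software this design follows; distance ties break toward the
smaller id so matching is reproducible. Perfectly separated ages are
rejected (the logistic MLE does not exist there).

Matched cohorts are split 7:1:2 with sizes `train = floor(0.7n + 0.5)`,
`test = floor(0.2n)`, `val = n - train - test` — the rounding rule is
chosen so a cohort of 1234 splits into (864, 124, 246); it is one of
several rules consistent with that outcome.

## Augmentation

Four operators, applied on the fly during training, each with independent
probability 0.5 (on-the-fly augmentation is the norm for volumetric
training loops; nothing here is pre-materialized):

* lateral mirror flip;
* random affine: rotation up to ±10° per axis and zoom 0.9–1.1 about the
  volume centre, nearest-neighbour lookup so masks stay binary;
* cutout: one axis-aligned cuboid (up to a third of the side) zeroed,
  emulating missing bone;
* partial affine: a cubic sub-region is extracted, rotated/translated
  within small ranges, and written back in place, emulating a displaced
  fracture fragment; voxels outside the region are untouched.

The numeric ranges are declared configuration — "realistic limits" for
skulls — not measured values. Every stochastic operator logs its sampled
parameters (cuboid coordinates, angles, shifts) so tests can verify the
exact voxels touched.

## The synthetic cohort generator

Real postmortem CT archives are not redistributable, so the generator
produces what the analysis *assumes*: binary cubes containing a hollow
spherical cranial shell, a hollow half-superellipsoid "mandible" whose
cross-section exponent morphs from rounded (2) to square (8) with an
angularity parameter, and a sagittal ridge crest. The sex signal is
concentrated in the mandible: per-specimen angularity is drawn from
sex-conditional normals whose means are `class_gap` apart (default 0.6,
SD 0.12). The ridge is a deliberately weak secondary signal (males express
the full amplitude, females 85%); measured per-patch effect sizes keep the
mandible patch the dominant discriminator by roughly a factor of two to
three. Putrefaction is emulated by deleting each foreground voxel with
probability 0.05 and injury by zeroing one random cuboid in 10% of
specimens — rates chosen once as plausible for a forensic case mix. Ages
default to a shared truncated normal (mean 75, SD 12, truncated to 18–100)
for both sexes, mirroring a post-matching age distribution; a per-sex shift
is available to exercise the matcher.

Every specimen derives its own RNG stream from `(cohort_seed, id)`, so
cohorts are reproducible independent of generation order, and identical
`(params, sex, age, seed)` reproduce a volume bit for bit.

**What passing tests on synthetic data do and do not show.** The generator
reproduces the *statistical structure* the method relies on — a localized
two-class shape difference inside a larger uninformative structure, plus
realistic nuisance noise — so tests demonstrate that the pipeline can
learn and localize such a signal. They say nothing about the effect size
of real human dimorphism: the synthetic class gap is a free design choice
and must not be read as anatomically calibrated.

## Evaluation and interpretation

Metrics use female as the positive class: accuracy $(TP+TN)/n$,
sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, kept at full precision
internally and displayed at two decimals (half-up). A metric with a zero
denominator is reported as `NA`, never as 0. Differences in metrics
between two raters on same-size test sets get an unpaired two-proportion
Wald interval without continuity correction; the method name is carried in
the output because paired per-case agreement data would permit (and a GUI
might compute) different intervals.

For interpretation, each patch is multiplied by its attention weight and
scattered back to its grid origin, producing a volume whose intensity maps
where the model looked; it exports as NIfTI plus orthogonal PNG views.

## Desk-scale experiment and problem sizes

`run_desk_experiment()` is the end-to-end study at package scale: 100
specimens per sex at $60^3$, 1:1 matching (caliper 0.2 SD), a 7:1:2 split,
27-patch bags, the reference encoder, and the optimization settings above
with the epoch cap lowered to 500. These sizes were chosen so the whole
experiment — data synthesis through training to evaluation — completes in
minutes on a single CPU core while preserving the bag topology (27 patches
per volume) of the full-scale design; early stopping at patience 50 halts
training well before the cap in typical runs, and the best-validation model
is returned either way. The companion `run_signal_experiment()` trains on synthetic
single-signal bags where exactly one patch carries a class-dependent
pattern, the cleanest setting in which attention should find the signal
patch.

On attention localization: with a clean geometric signal the maximum
attention weight lands on the mandible-bearing patch for essentially all
correctly classified test bags of both sexes. Under porosity and defect
noise this behaviour is seed-dependent: in most runs both the rounded and
the angular mandible morph acquire detectors and both sexes localize on
the mandible patch, but in some runs only one morph does — the bag-level
loss saturates once the classes separate, attention for the other sex
drifts to an arbitrary patch, and no gradient pressure remains to correct
it. This is a known property of attention-MIL (attention is only
guaranteed to localize the evidence the classifier actually uses), and the
package reports the localization rate over all correctly classified bags,
the stricter reading, rather than per-class rates.

## Known limitations

* The reference encoder is sized for $20^3$ patches; $100^3$ patches work
  through the same contract but are not the tested configuration.
* Attention heatmaps are patch-resolution (the model's evidence), not
  voxel-resolution saliency.
* The two-proportion interval is unpaired; published paired comparisons on
  one test set are not exactly reproducible without per-case agreement
  data.
* Synthetic skulls are statistical stand-ins, not anatomical models; no
  conclusion about real dimorphism effect sizes follows from them.
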