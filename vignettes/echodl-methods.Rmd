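---
title: "Data-efficient deep learning for echocardiogram-like images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-efficient deep learning for echocardiogram-like images: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Echocardiography produces grayscale still frames from a dozen-plus standard
acquisition orientations ("views"). Two classification tasks recur: deciding
which view a frame shows, and — within the apical four-chamber (a4c) view —
deciding whether the left ventricle (LV) is hypertrophic (LVH), i.e. whether
its myocardial wall is pathologically thickened. Labeled clinical data is
scarce and expensive, so this package implements two data-efficient
strategies and the infrastructure to study them:

1. **A supervised pipeline**: a modified U-Net segments the relevant
   structure (first the sector-shaped field of view, then the LV), the
   predicted mask is multiplied into the image so downstream models never
   see off-sector clutter, and a VGG-style CNN classifies the masked image.
   The disease classifier is initialised from the view classifier by
   two-stage transfer learning.
2. **A semi-supervised GAN (SSGAN)**: a two-headed discriminator doubles as
   a K-class classifier and learns from labeled, unlabeled and generated
   images through a summed three-term loss, while the generator is trained
   by feature matching.

Clinical echo archives are private, so the package bundles a synthetic
ultrasound-phantom generator that reproduces the *structure* of the problem
and serves as the benchmark for every test.

## The phantom generator

`phantom_spec()` / `render_phantom()` draw a bright, speckled, sector-shaped
field of view (FoV) on a black background, dark elliptical "chambers" whose
arrangement defines the view class, and an optional metadata band of bright
glyph blocks along the top 8% of rows, outside the sector — the clutter FoV
masking should remove. The LV-bearing class draws its LV as a bright
myocardial ring around a dark cavity; the wall thickness, as a fraction of
the LV radius, is drawn from `(0.12, 0.20)` for normal and `(0.30, 0.45)`
for LVH anatomy. Because the LVH minimum exceeds the normal maximum, the
classes are separable by construction, and a threshold on ring area
achieves perfect accuracy on ground-truth masks — the sanity floor any
learned classifier should approach. LVH is deliberately the *only*
covariate separating the classes, so phantom experiments isolate that
learning signal.

Acquisition variability is emulated at the study level: sector half-angle
±4°, sector tilt ±8°, chamber centres jittered by a Gaussian of 2.5% of the
frame, chamber axes scaled by ±15%, global intensity gain in (0.75, 1.15),
and unit-mean multiplicative gamma speckle with standard deviation 0.45
inside the sector. Frames of one study share this anatomy up to a small
frame-level jitter, mimicking consecutive frames of one acquisition. The
default four chamber layouts overlap in sub-structure (the three- and
four-chamber classes share ellipses), so views confuse under jitter the way
structurally similar clinical views do; up to 15 layouts are available.

LVH status is allocated to LV-view studies by exact quota
(`round(fraction * n)`), not by Bernoulli draws, so the intended roughly
4:1 normal:LVH imbalance holds exactly even in small datasets.

What the phantoms do **not** emulate: physically realistic speckle
statistics and attenuation, probe-dependent post-processing, Doppler or
m-mode waveforms, anatomical co-variation (body habitus, pathology other
than wall thickness), and inter-observer label noise. Passing phantom tests
therefore demonstrates that the algorithms and their implementation behave
as designed — not that the reported accuracies transfer to clinical data.

## Data handling conventions

- Intensities live in `[0, 1]`; conversion to `[-1, 1]` happens only at the
  GAN boundary (`to_gan_range()`), because the generator ends in Tanh.
- `resize_nearest()` uses the floor-index convention
  `src = floor(i * H / target)`: pure index selection, never interpolation,
  so no new intensity values appear.
- `split_by_study()` assigns whole studies to train/val/test with a seeded
  shuffle and largest-remainder quota on study counts — deterministic, and
  exact at round numbers (100 studies at 0.74/0.11/0.15 give 74/11/15).
  Frames of one patient never straddle the split boundary.
- `augment()` draws rotation uniform within ±`max_rotation` degrees and
  height/width shifts uniform within ±`max_shift` of each dimension
  (rounded to whole pixels), resamples nearest-neighbour and fills vacated
  pixels with 0 (black, like the echo background). Defaults are 10° and 10%.

## The segmenter

`build_unet()` constructs a contracting/expanding U-Net with skip
concatenations: per level two 3×3 convolutions (batch norm, ReLU) and 2×2
max pooling, filters doubling from `base_filters` and capped below 1024 —
the widest stage of the original architecture is removed — with dropout at
the end of the bottleneck, immediately before the first up-sampling
convolution, and a 1×1 convolution plus per-pixel softmax at the output.
The exact per-level filter table is a declared construction rule
(double-and-cap), not a reconstruction of any published table.

Training minimises the mean per-pixel cross-entropy (`-log p(true
channel)`, natural log, probabilities clamped at `1e-7`) with Adam; the
canonical schedule is 50 epochs at learning rate `1e-4` with a per-epoch
multiplicative decay of 0.93 (`seg_schedule()` defaults). The desk-scale
benchmark runs in this package use 6 epochs at `3e-4` with the same decay —
a proportionally larger rate for a schedule roughly one-eighth as long —
on 200 training phantoms at 64×80.

`predict_mask()` takes the per-pixel argmax with ties broken toward
background: a pixel enters the mask only when its foreground probability
strictly exceeds 0.5.

## The supervised classifier

`default_config_for_resolution()` encodes three design rules: 3×3 filters,
same padding, stride 1 and 2×2 pooling everywhere; max pooling at 60×80 and
above, average pooling below; 7×7 filters for the first two convolution
layers at 240×320 (a 3×3 patch of so large an image carries too little
context); and average pooling whenever the input is mask-preprocessed.
Block depth scales with `log2` of the smaller input dimension and filters
double per block from 8, capped at 64. Each convolution is followed by
batch norm and ReLU; the fully-connected head carries batch norm, ReLU,
dropout 0.4 and L2 weight decay 0.03, with Xavier-uniform initialisation;
the final layer is a softmax.

Training (`train_cnn()`) minimises categorical cross-entropy with Adam at
`lr0 = 0.02` decayed by 0.85 per epoch, augments training batches only, and
stops early once validation loss has failed to *strictly* improve on the
running best for two consecutive epochs, restoring the
best-validation-loss weights. Batch size defaults to 32 — a fixed choice
for determinism where the original recipe tuned it per resolution to the
GPU. The Adam β parameters stay at their defaults; the stated learning
rate and decay override only the step size.

`two_stage_transfer()` adapts a trained view classifier to the binary LVH
task: stage 1 freezes every convolutional parameter and trains a fresh
Xavier-initialised head (canonically 20 epochs at `lr0 = 0.025`, decay
0.85); stage 2 freezes the head and fine-tunes the convolutions
(`lr0 = 0.001`, decay 0.9). The freezes are exact — bit-identical
parameters — which the tests assert. Batch-norm *running statistics* in a
frozen block may still drift, as in classic Keras-style freezing; the
contract covers parameters. The binary objective is implemented as
two-class softmax cross-entropy, which is numerically identical to binary
cross-entropy on a sigmoid parameterisation.

`ensemble_predict()` averages probability vectors arithmetically, and
`resolution_study()` trains one default model per resolution on identically
split data, reporting validation accuracy and measured seconds per epoch.

## The semi-supervised GAN

The discriminator (`build_discriminator()`) stacks blocks of three
convolutions — two stride-1 and one downstride-2 — with batch norm after
every convolution, dropout after every downstride convolution and
leaky-ReLU activations; all filters are 3×3 except the last convolution,
a full-field convolution that collapses the remaining spatial map into the
penultimate feature vector. Two heads share those features: a K-class
softmax and a real/fake sigmoid emitting a score `s`.

The probability that an image is generated is realised as
`p(y = K+1 | x) = 1 - s`. The loss system is then

- supervised: `-E log p(y | x, y < K+1)` — softmax cross-entropy on labeled
  images;
- unsupervised: `-E log[1 - p(y = K+1 | x)] = -E log s` on real unlabeled
  images;
- generated: `-E log p(y = K+1 | x) = -E log(1 - s)` on generator output;

and their plain sum is the quantity one discriminator update minimises.
Each iteration performs three forward passes (labeled, unlabeled,
generated) whose gradients are accumulated into a single backpropagation
step, then one generator step on the feature-matching loss: the mean
squared difference between the *batch-mean* penultimate features of a fake
and a real batch (the batch-mean reading of feature matching from the
semi-supervised GAN literature; a per-sample pairing would be the other
admissible reading). An epoch is defined by the unlabeled set, so labeled
batches cycle many times per epoch. Both networks use Adam at a constant
`3e-4`; batch size defaults to 32.

The generator starts from a 1×1×`noise_dim` Gaussian seed map (default
`noise_dim = 100`) and applies stride-2 transposed convolutions with 4×4
kernels, batch norm and ReLU on intermediate layers and Tanh at the output;
seven layers reach 128×128, centrally cropped to the canonical 110×110.
Layer widths halve toward the output from `gen_base_filters * 2^(L-2)`,
floored at 8 and capped at 64 channels. Phantom benchmarks render at the
standard 64×80 and downsample to a 28×28 square with five generator layers
(32×32 pre-crop), mirroring the acquire-then-downsample protocol in which
full frames are squashed to a small square before adversarial training.
Images are single-channel: clinical stills are grayscale.

One batch-norm subtlety matters for evaluation: the discriminator's
*running* statistics are what its classifier head uses at test time, so
they are updated only on real batches — stat tracking is frozen while
generated batches pass through. Without this the running statistics blend
fake-image statistics and evaluation-mode accuracy becomes erratic.

Because the labeled set at low label counts is tiny and cycles hundreds of
times per epoch, the package augments the labeled batches with the same
rotation/shift policy as the supervised recipe (configurable in
`gan_config()`, disable with `max_rotation = 0, max_shift = 0`). Without
it the classifier head simply memorises the handful of labeled images; with
it, the supervised and semi-supervised arms of any comparison also share
one augmentation policy.

`label_efficiency_curve()` keeps exactly *n* labels per class — selecting
whole studies before trimming, so labeling respects patient grouping —
treats the remainder as unlabeled, trains, and evaluates on a fixed
held-out test set.

An empty unlabeled set degrades to supervised-only training of the
classifier head with a warning.

## The routing pipeline

`run_pipeline()` fixes the stage order: resize to the segmenter's
resolution, predict and apply the FoV mask, classify the view on the masked
image (argmax, ties to the lowest class index), and, when the routing table
fires for the predicted view, predict the LV mask *on the raw image* (the
routing diagram feeds the segmenter from the input, not from the
FoV-masked image), apply it, and run the disease classifier. Only the
LV-bearing class routes by default. Every stage is deterministic given the
models, and the no-pixels-outside-the-mask property is asserted at each
masking boundary in the tests.

## Evaluation

`eval_report()` collects accuracy, per-class accuracy, a row-normalised
confusion matrix (empty true classes give zero rows with a warning, never
`NaN`), F1 (positive-class for binary tasks with LVH = class 1, macro
otherwise), sensitivity/specificity for binary tasks, and a percentile
bootstrap confidence interval for accuracy — pairs resampled with
replacement, interval at the `(1±level)/2` quantiles. Percentile (not BCa)
is used because nothing more specific is required, and resampling is at the
pair level, not the study level; since frames within a study correlate,
pair-level intervals are somewhat anti-conservative — a known limitation.
Both the `(low, high)` pair and the half-width are reported so no
convention is imposed on ± notation.

## Numerical choices

- Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside every logarithm.
- Softmax is computed with the max-subtraction trick.
- Mask argmax ties break toward background; view argmax ties toward the
  lowest class index (`which.max`).
- Batch norm uses biased batch variance, `eps = 1e-5`, momentum 0.9 for the
  running statistics used at evaluation.
- Largest-remainder quota resolves split rounding; `round()` resolves the
  LVH quota.
- All randomness — weight initialisation, shuffling, dropout, augmentation,
  noise, bootstrap — flows through R's RNG, so one `set.seed()` (or the
  `seed` fields of the config/schedule objects) reproduces a run bit-for-bit
  on one thread.

## The engine

No deep-learning framework is used: the package carries its own small CPU
engine — convolution, transposed convolution, 2×2 pooling and batch-norm
kernels in RcppArmadillo (the whole minibatch is lowered by im2col into one
GEMM), with layers, Adam and the training loops in R. The engine's
gradients are validated against central finite differences and its
convolutions against direct nested-loop oracles in the test suite. This
keeps every result reproducible from a single seed with no external runtime.

## Problem sizes used by the tests and the acceptance script

The bundled benchmarks are desk-scale by design: segmentation trains on 200
phantoms at 64×80 for 6 epochs (10 for the smaller, harder LV target); the
view classifiers on 1000 phantoms (500 two-frame studies, 70/10/20 study
split) for up to 9–10 epochs with early stopping; LVH transfer on 240
LV-masked phantoms for 4+4 epochs; the SSGAN comparison on 10 labels/class
plus 2000 unlabeled 28×28 phantoms (5 epochs in the test suite, 10 in the
acceptance script) against a supervised baseline trained on the same 40
images; the label-efficiency curve on a 200-image labeled pool plus 300
unlabeled at 1/5/15 labels per class for 2 epochs. These sizes are the
package's standard benchmark configuration; all are parameters, and larger
runs only require larger inputs.

A candid note on the semi-supervised comparison at this scale. One epoch
here is 63 iterations, where the original training regime ran thousands of
iterations per epoch to convergence at the same constant learning rate of
`3e-4`; a desk-scale run is therefore far from the converged regime. At
the same time the 4-class phantom task is geometrically simple enough that
a supervised CNN with the standard augmentation recipe generalises
strongly from 40 images. The package keeps both sides honest — the
baseline is trained with the full supervised recipe, and the GAN follows
the stated protocol — and reports the comparison as measured: the GAN
classifier learns far above chance from its 40 labels plus the unlabeled
pool, and on some label draws clearly beats the baseline, but its median
advantage at these budgets is not the stable multi-point margin the
converged large-scale setting exhibits. The label-efficiency *trend*
(accuracy rising with labels per class) is the robust desk-scale
signature.

## Known limitations

- Phantom realism, as above: passing tests validate the machinery, not
  clinical performance.
- The engine is CPU-only and single-threaded by design; it is meant for
  desk-scale experiments, not large-scale training.
- The SSGAN is trained without the stabilisation tricks of later
  literature (conditioned noise, spectral or other normalisation, robust
  losses); at very small label counts its accuracy fluctuates across
  epochs, which the label-efficiency harness absorbs by reporting medians
  across seeds.
- Dual-mode frames (two sectors side by side) are not modelled; each
  phantom has a single FoV.
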