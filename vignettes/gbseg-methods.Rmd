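---
title: "Methods: multi-scale channel attention U-Nets for gallbladder CT segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale channel attention U-Nets for gallbladder CT segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gbseg)
```

## The problem

The gallbladder is a small, hypodense organ adjacent to the liver. On an
axial abdominal CT slice it typically occupies well under one percent of the
pixels — in clinical gallbladder cohorts the foreground fraction is around
0.55% — and its boundary against liver parenchyma is low-contrast and
variable. Automatic delineation matters for radiotherapy planning of liver
tumours, where the gallbladder is an organ at risk, but the combination of
extreme class imbalance, small object size and similar-looking neighbouring
structures makes it a hard target for a plain encoder–decoder network.

`gbseg` implements a family of 2D segmentation networks for this problem
together with everything needed to train and judge them:

* **U-Net** — the classic encoder–decoder with skip connections, pinned to
  an exact configuration (below);
* **SEU-Net** — the same network with squeeze-and-excitation (cSE) channel
  attention appended to every encoder stage;
* **MCAU-Net** — the package's main model: the first one to three encoder
  stages are replaced by *multi-scale channel attention (MCA) blocks* and
  the decoder gains batch-normalized residual stages.

Because clinical CT with expert gallbladder contours is not publicly
shareable, the package also ships a seeded synthetic phantom generator that
reproduces the statistical shape of the task (a single small hypodense
ellipse inside a textured liver-like region, distractors included), so the
entire pipeline is exercisable and testable without patient data.

## The pinned baseline U-Net

The baseline is fixed to: 1 input channel; five encoder stages with channel
widths 16/32/64/128/256; two same-padded, biased 3×3 convolutions with ReLU
per stage; 2×2 max-pooling between stages; a decoder mirroring the encoder
with biased 2×2 stride-2 transposed convolutions, skip concatenation and two
3×3 convolutions per stage; a final biased 1×1 convolution with a sigmoid;
no normalization layers anywhere. This configuration has exactly
**1,940,817** parameters, all trainable — the reference count for this
architecture family — and `count_parameters(build_unet())` reproduces it to
the digit. The count is independent of the input size (the network is fully
convolutional); inputs must be divisible by 2^4 = 16.

## The MCA block

An MCA block replaces the two convolutions of an encoder stage and has two
halves, each of which can be disabled independently for ablations:

* **Multi-scale feature extraction.** Three parallel same-padded biased
  convolutions with kernel sizes 3/5/7 (alternatively 5/7/9), each emitting
  the stage's full channel count with ReLU; their concatenation (3C
  channels) is reduced back to C channels by a biased 1×1 convolution with
  ReLU. The restoration to C channels means the block is a drop-in
  replacement for the baseline stage. Larger kernel sets strictly increase
  the parameter count, which is one reason the 3/5/7 set is the default.
* **Multi-scale channel attention.** The block average-pools its feature
  map with non-overlapping windows of size (= stride) 2 and 4, takes global
  average descriptors of the original and both pooled maps (three length-C
  vectors), merges them, and passes the merged descriptor through a cSE
  excitation — a C→C/r fully connected layer with ReLU, then C/r→C with a
  sigmoid — whose output gates the channels of the feature map.

Three merge rules are provided: element-wise **mean** (default), **sum**,
and **concatenation** (which widens the excitation input to 3C). Mean was
chosen as the default because it is dimension-preserving and symmetric in
the three scales; for a spatially constant input the three descriptors
coincide and merging is a no-op, which is the behaviour one wants from a
"multi-scale summary". The attention weights are computed from the output
of the feature-extraction half (not from the block input); with gates
forced to 1 the block provably reduces to its attention-free form, a
property the test suite checks numerically.

Design points the architecture description leaves open were resolved as
follows, and are exposed as configuration rather than hard-coded:

* **Block placement.** With n blocks, the *shallowest* n encoder stages use
  MCA blocks (stage 1; stages 1–2; stages 1–3). Shallow stages see the
  highest resolution, which is where 5×5/7×7 kernels buy the most spatial
  context per parameter; deep placement would also grow the parameter count
  quadratically in the wider channels.
* **Excitation reduction.** r = 4. The shallow stages of the default
  schedule have 16 channels (8 in the desk-scale configuration), so the
  common r = 16 would collapse the bottleneck to a single unit.
* **Decoder.** MCAU-Net decoder stages apply conv→BN→ReLU, conv→BN, add a
  1×1-convolution projection of the stage input, then ReLU — a standard
  pre-activation-style residual stage. Batch-norm running statistics
  (momentum 0.9, eps 1e-5) are the model's only non-trainable parameters,
  so `count_parameters()` reports a positive non-trainable count exactly
  when batch norm is present.

The reference configuration is MCAU-Net-2 (two blocks), which the
experiments behind this family found the best of the three variants.

## Losses

Training uses the soft Dice loss

$$L = 1 - \frac{2\sum_i p_i g_i + \epsilon}{\sum_i p_i + \sum_i g_i + \epsilon},$$

with `eps = 1e-6` by default (the constant only guards the empty-empty
denominator; any value small against the object size gives the same
optimum). With ~0.55% foreground, per-pixel losses are dominated by the
background; the Dice loss normalizes by object size and is the reason the
network starts segmenting the phantom gallbladder within a few epochs. The
loss is computed **per image and averaged over the batch** rather than
pooled across the batch, preserving each sample's imbalance semantics; the
two conventions differ whenever object sizes vary within a batch. Binary
cross-entropy (probabilities clamped to `[1e-7, 1 - 1e-7]`) is provided as
the comparator objective.

## Training recipe

`training_preset()` carries the published full-scale hyperparameter table:
batch size 4, 80 epochs, and per-model schedules — U-Net 3e-6 with no decay
(empty decay cells are read as "no decay"), SEU-Net 6e-5 decayed ×0.96
every 1200 steps, and the MCAU variants 4e-4/5e-4/4e-4 decayed ×0.96 every
800 steps. The decay is *continuous* exponential,
`lr0 * rate^(step/steps)`, not staircase. The optimizer is Adam with
default moments (the optimizer is not specified by the architecture's
description; Adam is the de-facto default for this family), weights use He
initialisation, and checkpoint selection keeps the epoch with the best
validation mean DSC at threshold 0.5. Training is deterministic given the
config seed.

`smoke_config()` is the desk-scale counterpart used throughout the tests:
64×64 inputs, channel schedule 8/16/32/64/128, 10 epochs, batch 4, Dice
loss. It keeps the 5e-4 / 800 / 0.96 schedule for *every* variant so that
desk-scale comparisons reflect architecture, not per-model tuning (the
published per-model rates were tuned for full-scale clinical training; in
particular 3e-6 with no decay barely moves a freshly initialised network
within 10 desk-scale epochs).

## Preprocessing

The slice preparation chain is `to_hounsfield()` (affine rescale by
slope/intercept; identity for PNG input), `apply_window()` (clip to a
level/width HU band, map linearly to [0,1]), `equalize_adaptive()` (CLAHE
via `EBImage::clahe`) and `normalize01()` (min–max). The window defaults to
**level 60 HU, width 400 HU** — a standard abdominal soft-tissue window in
which liver (≈50–70 HU) and bile (≈0–20 HU) are both on-scale — and CLAHE
defaults to an 8×8 tile grid with clip limit 0.01 on the
fraction-of-tile-pixels scale. These are package defaults for a step whose
exact clinical settings are site-specific; both are configurable arguments.
A constant slice passes through CLAHE unchanged, and `normalize01()` maps a
constant grid to zeros rather than erroring, so padding-only slices cannot
abort a batch.

DICOM pixel data is supported through the same `to_hounsfield()` interface
(its slope/intercept arguments are exactly the DICOM rescale tags), but the
package reads PNG and NIfTI files only.

## Data handling

Splitting is **by patient**, never by slice: slices of one patient are
near-duplicates, and letting them straddle partitions would leak test
anatomy into training. Patient counts per partition follow
largest-remainder rounding of the requested fractions (default 54/6/40),
with remainder ties broken in the order train > val > test; patients are
sorted before the seeded shuffle so the split is invariant to sample order.

Augmentation composes one affine transform per draw — rotation (±15°),
shift (±10% of the side), horizontal shear (±10°) and isotropic zoom
(±10%) about the image centre — and applies the *identical* transform to
image (bilinear) and mask (nearest-neighbour, re-binarized at 0.5, so no
interpolation bleed can create foreground). Out-of-bounds regions fill
with 0 in both. The ranges are package defaults for operations whose
magnitudes are not standardised; `expand_training_set()` pre-expands a
training list reproducibly, and `augment_pair()` can equally be used
on-the-fly.

## The phantom generator

`make_phantom()` draws, deterministically from `(seed, index)`:

* a bright elliptical "liver" (base intensity 0.60) with smooth
  low-frequency texture on a darker background (0.25);
* the gallbladder: one filled ellipse of random eccentricity (axis ratio
  1.1–2.2) and orientation, placed inside the liver, whose continuous area
  equals `fg_fraction_target` of the image (default 0.55%); its intensity
  sits `contrast` (default 0.25) below liver parenchyma, hypodense as on
  real CT;
* distractor ellipses outside the liver, one deliberately matched to the
  gallbladder's intensity — the "similar neighbouring structure" failure
  mode real models hit;
* additive Gaussian noise (sd 0.05), clipped to [0,1].

The mask is the gallbladder ellipse only: binary and single-connected by
construction. Rasterisation at pixel centres makes the *expected* foreground
fraction equal the target; across 500 phantoms the mean fraction lands
within [0.40%, 0.70%], emulating the clinical imbalance statistic. Contrast
0.25 and noise 0.05 describe a post-windowing, post-CLAHE slice in which
the organ is visible but noisy — the regime the preparation chain aims for.

What the phantoms do **not** emulate: real CT noise correlation, partial
volume effects at the organ boundary, anatomical shape variation beyond
ellipses, inter-slice correlation within a patient, and contrast that
varies with acquisition protocol. Passing the phantom benchmark therefore
demonstrates that the implementation trains, discriminates context (ellipse
inside vs outside the liver), and ranks architectures at desk scale — not
that clinical-level accuracy transfers.

## Metrics

Per case (2D slice), on the binarized prediction (threshold 0.5, inclusive):
DSC, JSC, PPV, SE, the symmetric Hausdorff distance, RVD and VOE.
Conventions:

* **HD** is the plain symmetric Hausdorff distance between foreground point
  sets, Euclidean, in pixel units (slice spacing is not assumed known); an
  `hd95` percentile variant is available but off by default.
* **RVD** is reported as an absolute value by default (0 = ideal); a signed
  variant is a flag.
* **Empty prediction, non-empty truth:** dsc = jsc = ppv = se = 0, rvd = 1,
  voe = 1, hd = image diagonal. This keeps total failures inside the cohort
  statistics instead of discarding them.
* **Empty truth:** the case is flagged, excluded from aggregation, and
  counted in `n_excluded` (overlap metrics are undefined without ground
  truth).

`aggregate_metrics()` reports mean, sample SD (n−1; a single case reports
SD 0 with `sd_defined = FALSE`), median, type-7 quartiles and Tukey
whiskers (most extreme observations within 1.5 IQR) — the statistics behind
the usual cohort box plots. VOE ≡ 1 − JSC and DSC ≡ 2·JSC/(1+JSC) hold as
algebraic identities and are tested on every random pair.

## The network engine

No R deep-learning framework is available as a dependency, and the model
family *is* the package's subject, so the engine is implemented natively:
im2col + BLAS convolutions, non-overlapping 2×2 transposed convolutions,
max/average pooling and an inverse-mapped affine sampler in
Rcpp/RcppArmadillo, composed by a small reverse-mode tape in R (each
forward op records its inputs; backward replays the tape). Correctness is
established in the test suite by naive-loop convolution oracles and
finite-difference gradient checks through every architecture variant,
including batch norm in training mode and all three descriptor-merge rules.

## Problem sizes used in the checks

The packaged checks run on one CPU: the smoke training criterion uses 200
training / 40 validation phantoms at 64×64 for 10 epochs (MCAU-Net-2, base
8 channels, seed 42), reaching a best validation DSC above the 0.70
acceptability bar commonly cited for organ segmentation; the imbalance
check generates 500 phantoms at 256×256; the model-ordering benchmark
(`run_phantom_benchmark()`) trains U-Net and MCAU-Net-2 for 8 epochs on a
fixed 120/24/40 phantom split over three seeds and requires MCAU-Net-2's
mean test DSC to stay within 0.02 of (or above) the baseline's. These sizes
were chosen as the smallest at which the respective properties are stable
across seeds; the clinical-scale effect sizes (e.g. a +0.06 DSC margin on
patient CT) are *not* reproducible on synthetic phantoms, where both
architectures typically segment well, and the benchmark therefore checks
ordering, not margin.

## Known limitations

* 2D slices only; no 3D context, resampling or registration.
* The exact published parameter counts of SEU-Net and MCAU-Net depend on
  architecture details (SE reduction, normalization placement, branch
  widths) that are not recoverable; the package pins its own documented
  choices and checks the published *ordering* (U-Net < SEU-Net; U-Net <
  MCAU-Net < the 103M transformer hybrid) instead.
* Batch-norm behaviour with batch size 1 degenerates (a batch of one has
  zero variance per channel); use batch size ≥ 2 for MCAU variants.
* The engine is CPU-only and tuned for desk-scale experiments, not for
  full-resolution clinical training runs.
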