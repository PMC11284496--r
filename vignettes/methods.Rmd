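---
title: "Multi-scale attention segmentation of prostate MRI lesions: models, phantoms and metrics"
author: "prolesaNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale attention segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Delineating prostate cancer lesions on biparametric MRI (T2-weighted, ADC
and high-b-value DWI) is hard because lesions are small relative to the
gland, their contrast differs across sequences, and their sizes span more
than an order of magnitude. Architectures that pool aggressively lose the
small lesions; architectures that do not cannot see enough context for the
large ones. The networks in this package address that tension with two
attention mechanisms that operate *across* adjacent resolutions rather
than within a single scale.

## The model family

All twelve variants share one encoder–decoder backbone operating on a
`(24, 192, 192, 3)` tensor (depth, height, width, channels at 3.0 × 0.5 ×
0.5 mm). The encoder applies convolution stages (kernel 3×3×3, instance
normalisation with learnable gain/shift, ReLU) separated by max-pooling
with the schedule (2,2,2), (2,2,2), (2,2,2), (1,2,2): depth 24 → 12 → 6 →
3 → 3, in-plane 192 → 12. The fourth transition does not pool the depth
axis so that 24 slices survive four poolings without fractional sizes. The
decoder mirrors the schedule with transposed convolutions whose kernel
equals the pooling factor. A pointwise convolution plus sigmoid produces
the voxelwise lesion probability; prediction thresholds at 0.5
(inclusive), with no connected-component postprocessing.

The *baseline family* uses a single convolution per stage; the *U-Net
family* uses two. On top of either backbone:

* **SE** — classic squeeze-and-excitation on each skip: channel scores
  `sigmoid(FC2(ReLU(FC1(GAP(x)))))` with reduction ratio r = 8.
* **AG** — classic additive attention gate: a single-channel map
  `sigmoid(psi(ReLU(Wg·g + Ws·s)))` rescales the skip features.
* **MSSE** — multi-scale SE. The previous level's skip output (the
  high-resolution residual) is brought to the current grid and channel
  count by a learnable kernel-1 convolution whose stride equals the
  pooling factor of that transition, added elementwise to the current
  residual (`FMA`), globally average-pooled, passed through the excitation
  pair C → C/8 → C, and the scores rescale `FMA`. Both excitation layers
  end in ReLU by default — deliberately unbounded, following the source
  description of the mechanism — and a config switch
  (`excitation = "sigmoid"`) restores the classic bounded ending. The top
  level has no higher-resolution predecessor, so MSSE degenerates to plain
  SE there, and successive MSSE outputs chain: each feeds both its decoder
  level and the next MSSE.
* **MSAG** — multi-scale attention gate on the decoder. Pointwise
  convolutions homogenise the encoder skip and the upsampled decoder
  features (`FPR`); their sum (`FMA`) is multiplied elementwise with
  `FPR`, softmaxed over all spatial positions per channel, condensed to a
  single channel by a pointwise convolution and squashed by a sigmoid.
  The resulting gate in (0, 1) multiplies `FPR`. Because the gated output
  already has the decoder width, the concatenation-reducing convolution is
  unnecessary: MSAG variants drop one decoder convolution per level
  (floored at one), which is where their parameter savings come from.
  At equal widths the full attention model is therefore *smaller* than
  the plain baseline.

One description of the multi-scale fusion is internally contradictory —
it calls a stride-2 reduction an "upsampling operation". We implement the
only geometry consistent with a stride-2, kernel-1 convolution and with
skip-connection shapes: the high-resolution residual is reduced to the
coarse grid, and fusion happens there.

### Width calibration

The published parameter counts are treated as ground truth for the default
configuration. With level widths shared across families the two counts
cannot both hold (the single-conv MSAG family is ~2.5× smaller at equal
widths), so each family carries its own calibrated vector, found by exact
integer search near a doubling progression:

| family | widths | parameters |
|---|---|---|
| single-conv (prolesa) | 48, 88, 177, 363, 750 | 16,544,129 |
| U-Net | 32, 69, 132, 223, 464 | 18,335,585 |

Counts include every trainable scalar: convolution and dense weights,
biases, and instance-norm gains/shifts. They are exact functions of the
configuration — independent of seed and batch size — and
`countParameters()` reproduces both numbers on every build.

### Initialisation and optimisation

He initialisation for convolutions and dense layers; the kernel-1
"identity" convolutions of MSSE/MSAG start as a partial identity plus
small noise, preserving their pass-through intent when channel counts
match. The head bias starts at the log-odds of a 1% foreground prior so
an untrained network predicts background — the standard stabilisation for
Dice-type losses on sparse targets. Training uses Adam (default learning
rate 1e-4; the overfit smoke runs use 1e-2) on soft-Dice plus voxelwise
binary cross-entropy, computed from logits for numerical stability. All
layers and their gradients run on a small reverse-mode tape with
GEMM-based 3D convolution kernels; gradients of every operation are
verified against central finite differences in the test suite.

## Preprocessing

The pipeline order is fixed: resample all five volumes to (3.0, 0.5, 0.5)
mm — trilinear for images, nearest-neighbour for masks, output shape
`round(shape · spacing_in / spacing_out)` rounded half away from zero —
then zero image voxels outside the whole gland, crop or pad to
(24, 192, 192) centred on the whole-gland centroid (zero-padding puts the
extra voxel on the high-index side), then min–max normalise each sequence
of each case to [0, 1] (a constant volume maps to zero rather than
raising). Labels are never masked or normalised. Centroid-centred
cropping keeps the gland in frame for any input size and reduces to the
central-half window when the input is exactly twice the target.
Interpolation orders are not specified by the source; trilinear/nearest
is the community default and keeps masks binary by construction.

A consequence of nearest-neighbour label resampling worth knowing: when
upsampling in-plane from 1.0 mm to 0.5 mm, a lesion's measured Feret
diameter can grow by up to one *native* voxel (the mask boundary
quantises to native voxel centres). The resampling-consistency property
therefore holds at one native in-plane voxel, not one target voxel.

## The synthetic phantom

Phantoms exist so that every stage is testable without external imaging
data. A case is an ellipsoidal gland (default semiaxes 18 × 24 × 26 mm)
centred in a (20, 160, 160) grid at native spacing (3, 1, 1) mm —
deliberately *not* the model spacing, so resampling is always exercised.
Each requested lesion is an ellipsoid whose two in-plane semiaxes equal
half the requested axial diameter; the through-plane semiaxis is half the
in-plane radius, capped at half the gland's z-semiaxis. Ellipsoids are
rasterised by voxel-centre inclusion (a voxel belongs iff its centre lies
inside the analytic surface) — unambiguous and reproducible. Lesion
centres are drawn uniformly in gland-normalised coordinates within the
ball that guarantees analytic containment, then snapped to the nearest
axial grid plane: with 3 mm slices, an unsnapped centre can fall between
slices and the measured diameter undershoots by up to 2 mm, whereas the
snapped generator recovers requested diameters within one in-plane voxel.
Lesions are re-drawn (up to 200 times) until they do not touch, so
connected-component analysis sees each lesion separately.

Channel intensities are piecewise constant — (background, gland, lesion)
= (60, 350, 140) for T2W, (500, 1600, 650) for ADC, (4, 14, 60) for DWI —
hypointense lesions on T2W/ADC, hyperintense on DWI, with ranges spanning
orders of magnitude so min–max normalisation is genuinely exercised.
`noiseSigma` adds Gaussian noise with standard deviation expressed as a
fraction of each channel's |gland − lesion| contrast (default 0.05, i.e.
5% of the deciding contrast — conservative relative to clinical SNR).
Cohorts apportion cases over the diameter strata 0–15 / 15–30 / >30 mm by
the largest-remainder rule (ties broken in stratum order); the default
mix (61.5%, 34%, 4.5%) mirrors the external-validation distribution
reported for the public cohort this emulates, and per-stratum diameters
are drawn uniformly within (6, 14.5), (15, 29) and (30.5, 36) mm.

What the phantom does *not* emulate: MRI physics (bias fields, Rician
noise, partial volume), anatomy beyond ellipsoids, scanner variation, or
inter-sequence misregistration. Passing tests therefore demonstrate that
the machinery — geometry, resampling, optimisation, metrics — is correct,
not that the trained networks transfer to clinical data.

## Metrics

Five metrics per case: Dice, recall and precision (voxel counting), and
Hausdorff / average symmetric surface distance in millimetres. A surface
voxel is a mask voxel with at least one background 6-neighbour
(out-of-grid counts as background); distances are Euclidean between voxel
centres. The implementation computes directed distances by sampling the
exact anisotropic Euclidean distance transform (Felzenszwalb lower
envelopes) of one surface at the other's voxels; the test suite checks it
against an independent brute-force all-pairs computation to 1e-9 mm.
Conventions: both masks empty → Dice 1, distances 0; exactly one empty →
distances +Inf, recall and precision 0. The Hausdorff distance is the
exact 100th-percentile variant (a worst case, not HD95). Aggregation uses
means for the overlap metrics and medians for the distance metrics — the
median is what keeps a report finite when a model produces an empty mask
and the distances degenerate to +Inf.

The lesion axial diameter is the per-component (26-connectivity) maximum
over axial slices of the in-plane Feret diameter (max pairwise distance
between voxel centres, convex hull first for speed); the case value is
the largest component's. Stratification puts d < 15 in "0–15",
15 ≤ d ≤ 30 in "15–30" (a lesion at exactly 15 mm is intermediate,
matching non-overlapping table ranges and the "less than 15 mm"
definition of small) and d > 30 in ">30".

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on CPU at sizes
chosen to exercise full fidelity where it matters and reduced geometry
where it does not: parameter counting uses the full default builds;
pipeline accounting preprocesses 82 phantom cases at the full
(24, 192, 192) geometry; metric oracles run on ≤ 8×12×12 grids (hundreds
to a thousand random mask pairs); forward-pass contracts use a 3-level
(8, 32, 32) geometry for all twelve variants; and the overfit capacity
check trains every variant on one noiseless (16, 64, 64) case with widths
(8, 16, 32), stopping as soon as training Dice reaches 0.8 (all variants
reach it in well under the 400-step budget). Full-scale training on
clinical cohorts is explicitly out of scope; none of the package's claims
depend on matching any particular training run.

## Known limitations

* The training loop is desk-scale: single-volume batches, no
  augmentation (hooks exist), no learning-rate schedule.
* MSSE's paper-literal ReLU excitation is unbounded; the boundedness
  guarantee ("gating never increases activation magnitude") holds for
  SE, AG and MSAG, not MSSE. Use `excitation = "sigmoid"` if bounded
  scores matter.
* Checkpoints store weights as gzipped text — portable and
  binary-free, but large for full-width models.
* The phantom's piecewise-constant contrast makes segmentation easier
  than clinical data; overfit checks validate optimisation machinery,
  not clinical performance.
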