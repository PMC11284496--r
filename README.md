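# prolesaNet

Multi-scale attention 3D networks for prostate MRI lesion segmentation,
implemented natively in R.

## What this is

Segmenting prostate cancer lesions on biparametric MRI (T2-weighted, ADC
and diffusion-weighted volumes) is dominated by two failure modes: small
lesions (< 15 mm axial diameter) vanish under pooling, and decoders fire
false-positive clusters far from the gland. ProLesA-Net addresses both
with attention mechanisms that fuse information *across* adjacent encoder
resolutions:

* **MSSE** (multi-scale squeeze-and-excitation): the previous encoder
  level's residual is brought to the current grid by a learnable kernel-1
  strided convolution, added to the current residual, and the fused map
  `FMA` is channel-recalibrated by an excitation pair
  `act(FC2(act(FC1(GAP(FMA)))))` with reduction ratio r = 8:
  `SEout = FMA ⊙ scores`.
* **MSAG** (multi-scale attention gate): with decoder features `FPR` and
  the encoder skip `SEout` homogenised by pointwise convolutions,
  `FMA = SEout∗I + FPR∗I`, a per-channel spatial softmax of `FMA ⊙ FPR`
  is condensed to one channel, and
  `out = sigmoid(conv₁(softmax(FMA ⊙ FPR))) ⊙ FPR`.
  Because the gated output keeps the decoder width, one decoder
  convolution per level is dropped — the attention pays for itself in
  parameters.

The package provides the full twelve-variant ablation ladder (baseline
and 3D U-Net backbones ± AG / SE / MSAG / MSSE), the fixed-geometry
preprocessing pipeline (resampling to 3.0 × 0.5 × 0.5 mm, whole-gland
masking, crop/pad to 24 × 192 × 192, per-sequence min-max normalisation),
a seeded synthetic phantom generator with controllable lesion-size
strata, a CPU training loop (Adam on soft-Dice + cross-entropy, with
gradients from a built-in reverse-mode tape over GEMM-based 3D
convolution kernels), and the five-metric evaluation protocol — Dice,
recall, precision, exact Hausdorff distance and average symmetric surface
distance in millimetres — with lesion-size-stratified mean/median
aggregation.

No external imaging data is needed anywhere: phantoms stand in for
patients, which makes every stage testable and every number below
reproducible from a seed.

## Worked example

```r
library(prolesaNet)

# a synthetic case: ellipsoidal gland, one 12 mm lesion, three channels
case <- generateCase(PhantomSpec(lesionDiametersMM = 12, seed = 7))
case
#> ProstateCase 'phantom-000007': T2W/ADC/DWI + WG and lesion masks, 20x160x160 @ 3 x 1 x 1 mm
#>   gland voxels: 15752, lesion voxels: 113

mi <- preprocessCase(case, PreprocessConfig())
dim(inputTensor(mi))
#> [1]  24 192 192   3

# the published parameter counts fall out of the calibrated defaults
countParameters(buildModel(ModelConfig("prolesa")))
#> [1] 16544129
countParameters(buildModel(ModelConfig("unet3d")))
#> [1] 18335585

# overfit one noiseless case at reduced geometry (a few seconds on CPU)
geo <- PreprocessConfig(targetSpacingMM = c(3, 1, 1), targetShape = c(16L, 64L, 64L))
mi2 <- preprocessCase(generateCase(PhantomSpec(gridShape = c(12L, 72L, 72L),
                                               glandSemiaxesMM = c(14, 22, 24),
                                               lesionDiametersMM = 14,
                                               noiseSigma = 0, seed = 5)), geo)
m <- buildModel(ModelConfig("prolesa", inputShape = c(16L, 64L, 64L),
                            levelWidths = c(8L, 16L, 32L),
                            poolFactors = list(c(2L, 2L, 2L), c(2L, 2L, 2L))))
fit <- trainModel(m, list(mi2), TrainConfig(learningRate = 1e-2,
                                            maxEpochs = 60L, targetDice = 0.8))
tail(trainHistory(fit), 2)
#>   epoch      loss train_dice
#> 5     5 0.7504716  0.6930693
#> 6     6 0.6895649  0.8123515

pred <- predictCase(fittedModel(fit), mi2)
caseMetrics(inputLabel(mi2), voxelValues(pred), spacing = c(3, 1, 1))
#>     id      dice hausdorff_mm    asd_mm    recall precision lesion_diameter_mm stratum
#> 1 case 0.8701299            3 0.2784493 0.8626609 0.8777293           13.60147    0-15
```

The training Dice history shows the optimisation converging on the one
case and stopping as soon as it clears the 0.8 target; the per-case
metric row reads: 87% volume overlap, worst surface error 3 mm (one
slice thickness), mean surface error 0.28 mm, and the ground-truth
lesion (13.6 mm measured Feret diameter) falls in the small-lesion
stratum.

An end-to-end demonstration — simulate 8 phantoms, preprocess, train,
predict, evaluate, with every artifact hashed in a run manifest:

```r
report <- runPipeline(defaultRunConfig(), "demo_run")
```

or from a shell via the bundled CLI:

```sh
Rscript inst/exec/prolesanet run-all --out-dir demo_run --seed 1
Rscript inst/exec/prolesanet build --variant prolesa --summary
```

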