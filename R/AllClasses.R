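#' @import methods
NULL

#' A 3D scalar image with physical voxel spacing
#'
#' The elementary container of the package: one scalar grid indexed
#' (depth, height, width) together with its voxel spacing in millimetres,
#' stored (z, y, x) to match the array axes. All preprocessing and the
#' distance-based evaluation metrics operate in these physical units.
#' Masks are flagged so that resampling can switch to nearest-neighbour
#' interpolation and keep them binary.
#'
#' @slot values numeric 3D array indexed (depth, height, width)
#' @slot spacing numeric length-3 voxel spacing in mm, (z, y, x)
#' @slot mask logical; \code{TRUE} for binary masks
#'
#' @examples
#' vol <- ImageVolume(array(rnorm(8 * 16 * 16), c(8, 16, 16)), c(3, 1, 1))
#' spacingMM(vol)
#' @export ImageVolume
#' @exportClass ImageVolume
setClass("ImageVolume",
         representation(values = "array", spacing = "numeric",
                        mask = "logical"))

setValidity("ImageVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array (depth, height, width)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (z, y, x) in mm")
  if (object@mask && !all(object@values %in% c(0, 1)))
    return("mask volumes must contain only 0 and 1")
  TRUE
})

#' @rdname ImageVolume-class
#' @param values numeric 3D array (depth, height, width)
#' @param spacing numeric length-3, mm per voxel (z, y, x)
#' @param mask logical, is this a binary mask
#' @export
ImageVolume <- function(values, spacing, mask = FALSE) {
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      mask = isTRUE(mask))
}

#' A patient case: three aligned MRI channels plus masks
#'
#' Holds the three co-registered biparametric MRI sequences (T2-weighted,
#' apparent diffusion coefficient and diffusion-weighted) together with the
#' whole-gland (WG) mask and the lesion mask, all on one grid. The channels
#' are assumed pre-registered to the T2W frame.
#'
#' @slot id character case identifier
#' @slot t2w,adc,dwi \linkS4class{ImageVolume} image channels
#' @slot wgMask \linkS4class{ImageVolume} binary whole-gland mask
#' @slot lesionMask \linkS4class{ImageVolume} binary lesion mask,
#'   voxelwise contained in the whole-gland mask
#' @export ProstateCase
#' @exportClass ProstateCase
setClass("ProstateCase",
         representation(id = "character", t2w = "ImageVolume",
                        adc = "ImageVolume", dwi = "ImageVolume",
                        wgMask = "ImageVolume", lesionMask = "ImageVolume"))

setValidity("ProstateCase", function(object) {
  vols <- list(object@t2w, object@adc, object@dwi, object@wgMask,
               object@lesionMask)
  d <- dim(object@t2w@values)
  sp <- object@t2w@spacing
  for (v in vols) {
    if (!identical(dim(v@values), d))
      return("all five volumes must share one grid shape")
    if (max(abs(v@spacing - sp)) > 1e-9)
      return("all five volumes must share one spacing")
  }
  if (!object@wgMask@mask || !object@lesionMask@mask)
    return("wgMask and lesionMask must be flagged as masks")
  if (any(object@lesionMask@values > object@wgMask@values))
    return("lesion mask must be voxelwise contained in the whole-gland mask")
  TRUE
})

#' @rdname ProstateCase-class
#' @param id case identifier
#' @param t2w,adc,dwi image channels (\linkS4class{ImageVolume})
#' @param wgMask,lesionMask binary masks (\linkS4class{ImageVolume})
#' @export
ProstateCase <- function(id, t2w, adc, dwi, wgMask, lesionMask) {
  new("ProstateCase", id = as.character(id), t2w = t2w, adc = adc, dwi = dwi,
      wgMask = wgMask, lesionMask = lesionMask)
}

#' Specification of a synthetic phantom case
#'
#' Describes one synthetic three-channel prostate-like case: an ellipsoidal
#' gland containing one or more ellipsoidal lesions with requested axial
#' diameters, rasterised by voxel-centre inclusion onto a grid with
#' anisotropic native spacing. Channel intensities are piecewise-constant
#' (background / gland / lesion) plus optional Gaussian noise; the default
#' contrast makes lesions hypointense on T2W and ADC and hyperintense on
#' DWI, and the three channels span ranges differing by orders of magnitude
#' so that min-max normalisation is genuinely exercised.
#'
#' @slot gridShape integer length-3 (depth, height, width), all >= 4
#' @slot spacingMM numeric length-3 native spacing (z, y, x) mm; the default
#'   (3, 1, 1) deliberately differs from the model spacing so resampling is
#'   always exercised
#' @slot glandSemiaxesMM numeric length-3 gland semiaxes (z, y, x) mm
#' @slot lesionDiametersMM numeric, requested lesion axial diameters in mm
#' @slot contrast 3x3 numeric matrix, rows (T2W, ADC, DWI), columns
#'   (background, gland, lesion), arbitrary intensity units
#' @slot noiseSigma additive Gaussian noise sd, expressed as a fraction of
#'   each channel's |gland - lesion| contrast
#' @slot seed integer RNG seed; a spec + seed fully determines the case
#' @export PhantomSpec
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(gridShape = "integer", spacingMM = "numeric",
                        glandSemiaxesMM = "numeric",
                        lesionDiametersMM = "numeric",
                        contrast = "matrix", noiseSigma = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    return("gridShape must be 3 integers, all >= 4")
  if (any(object@spacingMM <= 0)) return("spacingMM must be strictly positive")
  if (any(object@glandSemiaxesMM <= 0)) return("gland semiaxes must be positive")
  if (length(object@lesionDiametersMM) < 1L ||
      any(object@lesionDiametersMM <= 0))
    return("at least one positive lesion diameter is required")
  if (!all(dim(object@contrast) == c(3L, 3L)))
    return("contrast must be a 3x3 matrix (channels x background/gland/lesion)")
  if (object@noiseSigma < 0) return("noiseSigma must be non-negative")
  bad <- vapply(object@lesionDiametersMM, function(d) {
    ax <- lesionSemiaxes(d, object@glandSemiaxesMM)
    max(ax / object@glandSemiaxesMM) >= 1
  }, logical(1))
  if (any(bad))
    return(sprintf("lesion with diameter %.6g mm cannot fit inside the gland",
                   object@lesionDiametersMM[which(bad)[1]]))
  TRUE
})

.default_contrast <- function() {
  m <- rbind(t2w = c(60, 350, 140),     # lesion hypointense
             adc = c(500, 1600, 650),   # lesion hypointense
             dwi = c(4, 14, 60))        # lesion hyperintense
  colnames(m) <- c("background", "gland", "lesion")
  m
}

#' @rdname PhantomSpec-class
#' @param gridShape,spacingMM,glandSemiaxesMM,lesionDiametersMM,contrast,noiseSigma,seed
#'   see slot documentation
#' @export
PhantomSpec <- function(gridShape = c(20L, 160L, 160L),
                        spacingMM = c(3, 1, 1),
                        glandSemiaxesMM = c(18, 24, 26),
                        lesionDiametersMM = 10,
                        contrast = .default_contrast(),
                        noiseSigma = 0.05,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingMM = as.numeric(spacingMM),
      glandSemiaxesMM = as.numeric(glandSemiaxesMM),
      lesionDiametersMM = as.numeric(lesionDiametersMM),
      contrast = contrast, noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed))
}

#' Preprocessing configuration
#'
#' Fixed target geometry and options of the preprocessing pipeline:
#' resampling to uniform spacing, whole-gland masking, centre crop /
#' symmetric pad to a fixed shape, and per-sequence min-max normalisation
#' to [0, 1].
#'
#' @slot targetSpacingMM numeric (z, y, x) mm, default (3, 0.5, 0.5)
#' @slot targetShape integer (depth, height, width), default (24, 192, 192)
#' @slot applyWGMask logical, zero out voxels outside the whole gland
#' @export PreprocessConfig
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
         representation(targetSpacingMM = "numeric", targetShape = "integer",
                        applyWGMask = "logical"))

setValidity("PreprocessConfig", function(object) {
  if (any(object@targetSpacingMM <= 0)) return("target spacing must be positive")
  if (any(object@targetShape < 1L)) return("target shape must be positive")
  TRUE
})

#' @rdname PreprocessConfig-class
#' @param targetSpacingMM,targetShape,applyWGMask see slot documentation
#' @export
PreprocessConfig <- function(targetSpacingMM = c(3, 0.5, 0.5),
                             targetShape = c(24L, 192L, 192L),
                             applyWGMask = TRUE) {
  new("PreprocessConfig", targetSpacingMM = as.numeric(targetSpacingMM),
      targetShape = as.integer(targetShape), applyWGMask = isTRUE(applyWGMask))
}

#' Preprocessed model input
#'
#' The fixed-geometry network input produced by \code{\link{preprocessCase}}:
#' a (depth, height, width, 3) tensor in [0, 1] with channel order
#' (T2W, ADC, DWI) and the matching binary lesion label.
#'
#' @slot tensor numeric 4D array (depth, height, width, 3) in [0, 1]
#' @slot label numeric 3D binary array (depth, height, width)
#' @slot id character case id
#' @slot spacing numeric (z, y, x) mm of the target grid
#' @exportClass ModelInput
setClass("ModelInput",
         representation(tensor = "array", label = "array", id = "character",
                        spacing = "numeric"))

setValidity("ModelInput", function(object) {
  d <- dim(object@tensor)
  if (length(d) != 4L || d[4] != 3L)
    return("tensor must be (depth, height, width, 3)")
  if (!identical(dim(object@label), d[1:3]))
    return("label shape must match tensor spatial shape")
  if (min(object@tensor) < 0 || max(object@tensor) > 1)
    return("tensor values must lie in [0, 1]")
  if (!all(object@label %in% c(0, 1))) return("label must be binary")
  TRUE
})

#' Network configuration
#'
#' Fully determines an architecture of the ablation ladder: the backbone
#' family, the attention blocks used on the skip and decoder paths, the
#' per-level channel widths and the pooling schedule. Together with the
#' initialisation seed this fixes the exact trainable parameter count.
#'
#' Variants: \code{baseline}, \code{baseline+AG}, \code{baseline+SE},
#' \code{baseline+MSAG}, \code{baseline+MSSE}, \code{baseline+AG+SE},
#' \code{prolesa} (= baseline + MSAG + MSSE), \code{unet3d},
#' \code{unet3d+MSAG}, \code{unet3d+MSSE}, \code{unet3d+MSAG+MSSE},
#' \code{attention_unet3d}. The baseline family uses a single convolution
#' per stage; the U-Net family uses two.
#'
#' @slot variant character, one of the variants above
#' @slot inputShape integer (depth, height, width)
#' @slot inChannels integer, input channels (3 for T2W/ADC/DWI)
#' @slot levelWidths integer vector of channels per level, strictly
#'   increasing; \code{NA} selects the calibrated family default
#' @slot poolFactors list of integer (z, y, x) pooling factors per
#'   down-transition
#' @slot reductionRatio integer squeeze-and-excitation reduction ratio
#' @slot excitation character, activation after the second excitation layer
#'   in MSSE: \code{"relu"} (default) or \code{"sigmoid"}
#' @slot seed integer initialisation seed
#' @export ModelConfig
#' @exportClass ModelConfig
setClass("ModelConfig",
         representation(variant = "character", inputShape = "integer",
                        inChannels = "integer", levelWidths = "integer",
                        poolFactors = "list", reductionRatio = "integer",
                        excitation = "character", seed = "integer"))

modelVariants <- function() c("baseline", "baseline+AG", "baseline+SE",
                              "baseline+MSAG", "baseline+MSSE",
                              "baseline+AG+SE", "prolesa", "unet3d",
                              "unet3d+MSAG", "unet3d+MSSE",
                              "unet3d+MSAG+MSSE", "attention_unet3d")

setValidity("ModelConfig", function(object) {
  if (!object@variant %in% modelVariants())
    return(sprintf("unknown variant '%s'", object@variant))
  v <- object@levelWidths
  if (length(v) < 2L) return("at least 2 levels are required")
  if (any(diff(v) <= 0)) return("level widths must be strictly increasing")
  if (length(object@poolFactors) != length(v) - 1L)
    return("need one pooling factor triple per down-transition")
  pf <- vapply(object@poolFactors, function(f) as.integer(f), integer(3))
  tot <- apply(pf, 1, prod)
  for (ax in 1:3)
    if (object@inputShape[ax] %% tot[ax] != 0L)
      return(sprintf(
        "input axis %d (size %d) is not divisible by the pooling product %d",
        ax, object@inputShape[ax], tot[ax]))
  if (object@reductionRatio < 1L) return("reduction ratio must be >= 1")
  if (!object@excitation %in% c("relu", "sigmoid"))
    return("excitation must be 'relu' or 'sigmoid'")
  TRUE
})

# Calibrated default widths. The single-conv (baseline) family and the
# two-conv U-Net family use different vectors: these are the integer
# solutions for which the default builds reproduce the published trainable
# parameter counts (16,544,129 for prolesa and 18,335,585 for unet3d).
defaultLevelWidths <- function(variant) {
  if (grepl("^unet3d|^attention", variant)) c(32L, 69L, 132L, 223L, 464L)
  else c(48L, 88L, 177L, 363L, 750L)
}

defaultPoolFactors <- function(nlevels, inputShape = c(24L, 192L, 192L)) {
  base <- list(c(2L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L), c(1L, 2L, 2L))
  if (nlevels - 1L <= 4L) return(base[seq_len(nlevels - 1L)])
  c(base, rep(list(c(1L, 2L, 2L)), nlevels - 1L - 4L))
}

#' @rdname ModelConfig-class
#' @param variant,inputShape,inChannels,levelWidths,poolFactors,reductionRatio,excitation,seed
#'   see slot documentation
#' @export
ModelConfig <- function(variant = "prolesa",
                        inputShape = c(24L, 192L, 192L),
                        inChannels = 3L,
                        levelWidths = NULL,
                        poolFactors = NULL,
                        reductionRatio = 8L,
                        excitation = "relu",
                        seed = 1L) {
  if (is.null(levelWidths)) levelWidths <- defaultLevelWidths(variant)
  if (is.null(poolFactors))
    poolFactors <- defaultPoolFactors(length(levelWidths), inputShape)
  new("ModelConfig", variant = variant, inputShape = as.integer(inputShape),
      inChannels = as.integer(inChannels),
      levelWidths = as.integer(levelWidths),
      poolFactors = lapply(poolFactors, as.integer),
      reductionRatio = as.integer(reductionRatio),
      excitation = excitation, seed = as.integer(seed))
}

#' A built segmentation network
#'
#' Opaque handle around the parameter store and the architecture plan.
#' Use \code{\link{countParameters}}, \code{\link{modelForward}},
#' \code{\link{predictCase}} and \code{\link{trainModel}} to interact
#' with it.
#'
#' @slot config \linkS4class{ModelConfig}
#' @slot params environment mapping parameter names to numeric arrays
#' @exportClass SegModel
setClass("SegModel",
         representation(config = "ModelConfig", params = "environment"))

#' Training configuration
#'
#' @slot loss character: \code{"dice_bce"} (default), \code{"dice"} or
#'   \code{"bce"}
#' @slot learningRate numeric Adam step size, default 1e-4
#' @slot batchSize integer >= 1
#' @slot maxEpochs integer
#' @slot patience integer early-stop patience on validation Dice (NA
#'   disables)
#' @slot targetDice numeric; stop as soon as training Dice reaches this
#'   value (NA disables)
#' @slot seed integer
#' @slot deterministic logical; seeded shuffling and initialisation
#' @export TrainConfig
#' @exportClass TrainConfig
setClass("TrainConfig",
         representation(loss = "character", learningRate = "numeric",
                        batchSize = "integer", maxEpochs = "integer",
                        patience = "integer", targetDice = "numeric",
                        seed = "integer", deterministic = "logical"))

setValidity("TrainConfig", function(object) {
  if (!object@loss %in% c("dice_bce", "dice", "bce"))
    return("loss must be one of dice_bce, dice, bce")
  if (object@learningRate <= 0) return("learning rate must be positive")
  if (object@batchSize < 1L) return("batch size must be >= 1")
  if (object@maxEpochs < 0L) return("maxEpochs must be >= 0")
  TRUE
})

#' @rdname TrainConfig-class
#' @param loss,learningRate,batchSize,maxEpochs,patience,targetDice,seed,deterministic
#'   see slot documentation
#' @export
TrainConfig <- function(loss = "dice_bce", learningRate = 1e-4,
                        batchSize = 1L, maxEpochs = 50L, patience = NA_integer_,
                        targetDice = NA_real_, seed = 1L,
                        deterministic = TRUE) {
  new("TrainConfig", loss = loss, learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), targetDice = as.numeric(targetDice),
      seed = as.integer(seed), deterministic = isTRUE(deterministic))
}

#' Training result
#'
#' @slot model the fitted \linkS4class{SegModel}
#' @slot history data.frame with one row per epoch: \code{epoch},
#'   \code{loss}, \code{train_dice}
#' @slot config the \linkS4class{TrainConfig} used
#' @exportClass TrainResult
setClass("TrainResult",
         representation(model = "SegModel", history = "data.frame",
                        config = "TrainConfig"))
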