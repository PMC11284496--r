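# Generics, accessors and show methods for the core containers.

#' Voxel values of a volume
#' @param x an \linkS4class{ImageVolume}
#' @return numeric 3D array (depth, height, width)
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname voxelValues
#' @export
setMethod("voxelValues", "ImageVolume", function(x) x@values)

#' Voxel spacing in millimetres
#' @param x an \linkS4class{ImageVolume} or \linkS4class{ProstateCase}
#' @return numeric length-3 spacing (z, y, x) in mm
#' @export
setGeneric("spacingMM", function(x) standardGeneric("spacingMM"))

#' @rdname spacingMM
#' @export
setMethod("spacingMM", "ImageVolume", function(x) x@spacing)

#' @rdname spacingMM
#' @export
setMethod("spacingMM", "ProstateCase", function(x) x@t2w@spacing)

#' Is this volume a binary mask?
#' @param x an \linkS4class{ImageVolume}
#' @export
setGeneric("isMask", function(x) standardGeneric("isMask"))

#' @rdname isMask
#' @export
setMethod("isMask", "ImageVolume", function(x) x@mask)

#' Case identifier
#' @param x a \linkS4class{ProstateCase} or \linkS4class{ModelInput}
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname caseId
#' @export
setMethod("caseId", "ProstateCase", function(x) x@id)

#' @rdname caseId
#' @export
setMethod("caseId", "ModelInput", function(x) x@id)

#' Image channels of a case
#' @param x a \linkS4class{ProstateCase}
#' @return named list of \linkS4class{ImageVolume}s (t2w, adc, dwi)
#' @export
setGeneric("channelList", function(x) standardGeneric("channelList"))

#' @rdname channelList
#' @export
setMethod("channelList", "ProstateCase",
          function(x) list(t2w = x@t2w, adc = x@adc, dwi = x@dwi))

#' Whole-gland mask of a case
#' @param x a \linkS4class{ProstateCase}
#' @export
setGeneric("wgMask", function(x) standardGeneric("wgMask"))

#' @rdname wgMask
#' @export
setMethod("wgMask", "ProstateCase", function(x) x@wgMask)

#' Lesion mask of a case
#' @param x a \linkS4class{ProstateCase}
#' @export
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))

#' @rdname lesionMask
#' @export
setMethod("lesionMask", "ProstateCase", function(x) x@lesionMask)

#' Input tensor of a preprocessed case
#' @param x a \linkS4class{ModelInput}
#' @return numeric array (depth, height, width, 3)
#' @export
setGeneric("inputTensor", function(x) standardGeneric("inputTensor"))

#' @rdname inputTensor
#' @export
setMethod("inputTensor", "ModelInput", function(x) x@tensor)

#' Lesion label of a preprocessed case
#' @param x a \linkS4class{ModelInput}
#' @export
setGeneric("inputLabel", function(x) standardGeneric("inputLabel"))

#' @rdname inputLabel
#' @export
setMethod("inputLabel", "ModelInput", function(x) x@label)

#' Model configuration of a built network
#' @param x a \linkS4class{SegModel} or \linkS4class{TrainResult}
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "SegModel", function(x) x@config)

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "TrainResult", function(x) x@model@config)

#' Training history
#' @param x a \linkS4class{TrainResult}
#' @return data.frame with columns epoch, loss, train_dice
#' @export
setGeneric("trainHistory", function(x) standardGeneric("trainHistory"))

#' @rdname trainHistory
#' @export
setMethod("trainHistory", "TrainResult", function(x) x@history)

#' Fitted model of a training run
#' @param x a \linkS4class{TrainResult}
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))

#' @rdname fittedModel
#' @export
setMethod("fittedModel", "TrainResult", function(x) x@model)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume%s %dx%dx%d (depth x height x width), spacing %s mm\n",
              if (object@mask) " [mask]" else "", d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "ProstateCase", function(object) {
  d <- dim(object@t2w@values)
  cat(sprintf("ProstateCase '%s': T2W/ADC/DWI + WG and lesion masks, %dx%dx%d @ %s mm\n",
              object@id, d[1], d[2], d[3],
              paste(format(object@t2w@spacing), collapse = " x ")))
  cat(sprintf("  gland voxels: %d, lesion voxels: %d\n",
              sum(object@wgMask@values), sum(object@lesionMask@values)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: grid %s @ %s mm, gland semiaxes %s mm\n",
              paste(object@gridShape, collapse = "x"),
              paste(format(object@spacingMM), collapse = "x"),
              paste(format(object@glandSemiaxesMM), collapse = "x")))
  cat(sprintf("  lesions (axial diameter mm): %s; noise %.3g; seed %d\n",
              paste(format(object@lesionDiametersMM), collapse = ", "),
              object@noiseSigma, object@seed))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig '%s': input %s x %d, widths (%s), r = %d\n",
              object@variant, paste(object@inputShape, collapse = "x"),
              object@inChannels, paste(object@levelWidths, collapse = ", "),
              object@reductionRatio))
})

setMethod("show", "SegModel", function(object) {
  show(object@config)
  cat(sprintf("  trainable parameters: %s\n",
              format(countParameters(object), big.mark = ",")))
})

setMethod("show", "TrainResult", function(object) {
  h <- object@history
  cat(sprintf("TrainResult: %d epochs", nrow(h)))
  if (nrow(h))
    cat(sprintf(", final loss %.4g, final training Dice %.3f",
                h$loss[nrow(h)], h$train_dice[nrow(h)]))
  cat("\n")
})
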