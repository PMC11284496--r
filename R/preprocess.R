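# Preprocessing pipeline: resample to uniform spacing, whole-gland masking,
# centre crop / symmetric pad to a fixed shape, per-sequence min-max
# normalisation, and stacking into the three-channel model input.

# round half away from zero (shape arithmetic must be reproducible across
# platforms; R's round() uses banker's rounding)
roundHalfAway <- function(x) floor(x + 0.5)

#' Resample a volume to a target spacing
#'
#' Trilinear interpolation for images, nearest-neighbour for masks (masks
#' therefore stay binary). The output shape per axis is
#' \code{round(in_shape * in_spacing / target_spacing)} (half away from
#' zero), at least 1. Both grids share their origin at voxel (1,1,1); the
#' physical position of voxel i is (i-1) * spacing.
#'
#' @param vol an \linkS4class{ImageVolume}
#' @param targetSpacingMM numeric length-3 (z, y, x) in mm
#' @return resampled \linkS4class{ImageVolume}
#' @examples
#' v <- ImageVolume(array(1, c(12, 96, 96)), c(3, 1, 1))
#' dim(voxelValues(resampleToSpacing(v, c(3, 0.5, 0.5)))) # 12 192 192
#' @export
resampleToSpacing <- function(vol, targetSpacingMM) {
  targetSpacingMM <- as.numeric(targetSpacingMM)
  if (length(targetSpacingMM) != 3L || any(targetSpacingMM <= 0))
    stop("target spacing must be 3 strictly positive values")
  inDim <- dim(vol@values)
  outDim <- pmax(1L, as.integer(roundHalfAway(inDim * vol@spacing /
                                                targetSpacingMM)))
  out <- cpp_resample3d(vol@values, vol@spacing, targetSpacingMM,
                        outDim, vol@mask)
  ImageVolume(out, targetSpacingMM, mask = vol@mask)
}

#' Restrict an image to the whole gland
#'
#' Sets voxels outside the whole-gland mask to zero; voxels inside are
#' unchanged.
#'
#' @param image an \linkS4class{ImageVolume} (not a mask)
#' @param wg binary whole-gland \linkS4class{ImageVolume} on the same grid
#' @export
applyWgMask <- function(image, wg) {
  if (!identical(dim(image@values), dim(wg@values)))
    stop("image and whole-gland mask must share one grid shape")
  ImageVolume(image@values * wg@values, image@spacing, mask = image@mask)
}

#' Crop or pad a volume to a fixed shape
#'
#' Per axis: if the input is larger than the target, a centre crop is
#' taken (centred on \code{centerVoxel} when given, e.g. the whole-gland
#' centroid, else the geometric centre); if smaller, the volume is
#' zero-padded symmetrically with the extra voxel going to the high-index
#' side. Values inside the retained window are unchanged.
#'
#' @param vol an \linkS4class{ImageVolume}
#' @param targetShape integer length-3 (depth, height, width)
#' @param centerVoxel optional numeric length-3 crop centre (1-based voxel
#'   coordinates)
#' @export
cropOrPad <- function(vol, targetShape, centerVoxel = NULL) {
  targetShape <- as.integer(targetShape)
  inDim <- dim(vol@values)
  if (is.null(centerVoxel)) centerVoxel <- (inDim + 1) / 2
  src <- vector("list", 3)
  dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- inDim[ax]; t <- targetShape[ax]
    if (n >= t) {
      start <- floor(centerVoxel[ax] - t / 2)
      start <- min(max(start, 0L), n - t) # clamp window into the grid
      src[[ax]] <- seq.int(start + 1L, start + t)
      dst[[ax]] <- seq_len(t)
    } else {
      lo <- (t - n) %/% 2L # extra voxel on the high-index side
      src[[ax]] <- seq_len(n)
      dst[[ax]] <- seq.int(lo + 1L, lo + n)
    }
  }
  out <- array(0, targetShape)
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    vol@values[src[[1]], src[[2]], src[[3]]]
  ImageVolume(out, vol@spacing, mask = vol@mask)
}

#' Min-max normalise an image to [0, 1]
#'
#' \code{(v - min) / (max - min)} computed over the whole volume (per
#' sequence, per case). A constant volume maps to all zeros rather than
#' raising an error.
#'
#' @param vol an \linkS4class{ImageVolume} (not a mask)
#' @export
minmaxNormalize <- function(vol) {
  if (vol@mask) stop("refusing to normalise a mask")
  v <- vol@values
  lo <- min(v); hi <- max(v)
  out <- if (hi > lo) (v - lo) / (hi - lo) else array(0, dim(v))
  ImageVolume(out, vol@spacing)
}

maskCentroid <- function(mask) {
  idx <- which(mask@values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  colMeans(idx)
}

#' Preprocess a case into a model input
#'
#' Runs the full pipeline in order: resample all five volumes to the target
#' spacing (trilinear for images, nearest-neighbour for masks), zero out
#' image voxels outside the whole gland, crop or pad everything to the
#' target shape (crop centred on the whole-gland centroid), min-max
#' normalise each image channel, and stack channels (T2W, ADC, DWI). The
#' lesion label goes through resampling and crop/pad only -- never through
#' masking or normalisation.
#'
#' @param case a \linkS4class{ProstateCase}
#' @param cfg a \linkS4class{PreprocessConfig}
#' @return a \linkS4class{ModelInput}
#' @examples
#' case <- generateCase(PhantomSpec(seed = 3))
#' mi <- preprocessCase(case, PreprocessConfig())
#' dim(inputTensor(mi)) # 24 192 192 3
#' @export
preprocessCase <- function(case, cfg = PreprocessConfig()) {
  validObject(case)
  tryCatch({
    sp <- cfg@targetSpacingMM
    chans <- lapply(channelList(case), resampleToSpacing, targetSpacingMM = sp)
    wg <- resampleToSpacing(case@wgMask, sp)
    label <- resampleToSpacing(case@lesionMask, sp)
    if (cfg@applyWGMask)
      chans <- lapply(chans, applyWgMask, wg = wg)
    ctr <- maskCentroid(wg)
    chans <- lapply(chans, cropOrPad, targetShape = cfg@targetShape,
                    centerVoxel = ctr)
    label <- cropOrPad(label, cfg@targetShape, centerVoxel = ctr)
    chans <- lapply(chans, minmaxNormalize)
    tensor <- array(0, c(cfg@targetShape, 3L))
    for (i in 1:3) tensor[, , , i] <- chans[[i]]@values
    new("ModelInput", tensor = tensor, label = label@values,
        id = case@id, spacing = sp)
  }, error = function(e) {
    stop(sprintf("preprocessing case '%s' failed: %s", case@id,
                 conditionMessage(e)), call. = FALSE)
  })
}
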