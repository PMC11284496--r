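# NIfTI input/output. Arrays are stored (depth, height, width) in memory;
# on disk the conventional (x, y, z) order is used, so volumes are permuted
# on the way through and pixdim carries the spacing. On read, the NIfTI
# header is the source of truth for the spacing.

#' Write a volume as NIfTI
#'
#' @param vol an \linkS4class{ImageVolume}
#' @param path output path (".nii" or ".nii.gz")
#' @return the path, invisibly
#' @export
writeVolume <- function(vol, path) {
  arr <- aperm(vol@values, c(3, 2, 1)) # (x, y, z) on disk
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(vol@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file
#' @param mask logical: treat as a binary mask
#' @return an \linkS4class{ImageVolume}
#' @export
readVolume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  if (mask) arr <- array(as.numeric(arr != 0), dim(arr))
  ImageVolume(arr, rev(sp), mask = mask)
}

caseFileNames <- function(id)
  paste0(id, "_", c("t2w", "adc", "dwi", "wg", "lesion"), ".nii.gz")

#' Write a case as five NIfTI volumes
#'
#' Writes \code{<id>_t2w/adc/dwi/wg/lesion.nii.gz} into \code{dir}.
#'
#' @param case a \linkS4class{ProstateCase}
#' @param dir output directory (created if needed)
#' @return character vector of the five paths, invisibly
#' @export
writeCase <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, caseFileNames(case@id))
  vols <- list(case@t2w, case@adc, case@dwi, case@wgMask, case@lesionMask)
  for (i in seq_along(vols)) writeVolume(vols[[i]], paths[i])
  invisible(paths)
}

#' Read a case written by \code{\link{writeCase}}
#'
#' @param id case identifier
#' @param dir directory containing the five volumes
#' @return a \linkS4class{ProstateCase}
#' @export
readCase <- function(id, dir) {
  paths <- file.path(dir, caseFileNames(id))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("missing case file(s): %s", paste(missing, collapse = ", ")))
  ProstateCase(id,
               t2w = readVolume(paths[1]),
               adc = readVolume(paths[2]),
               dwi = readVolume(paths[3]),
               wgMask = readVolume(paths[4], mask = TRUE),
               lesionMask = readVolume(paths[5], mask = TRUE))
}

#' Save model weights and configuration
#'
#' Single-file checkpoint: a YAML header with the \linkS4class{ModelConfig}
#' followed by the flattened parameter vector, so a checkpoint fully
#' rebuilds the network.
#'
#' @param model a \linkS4class{SegModel}
#' @param path output file; a gzipped text format (YAML header + one value
#'   per line), readable anywhere
#' @return the path, invisibly
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config
  meta <- list(variant = cfg@variant, inputShape = cfg@inputShape,
               inChannels = cfg@inChannels, levelWidths = cfg@levelWidths,
               poolFactors = lapply(cfg@poolFactors, as.integer),
               reductionRatio = cfg@reductionRatio,
               excitation = cfg@excitation, seed = cfg@seed)
  shapes <- lapply(model@params$.order, function(nm) {
    v <- get(nm, envir = model@params)
    if (is.null(dim(v))) length(v) else dim(v)
  })
  names(shapes) <- model@params$.order
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines("# prolesaNet checkpoint v1", con)
  writeLines(yaml::as.yaml(list(config = meta, shapes = shapes)), con)
  writeLines("---values---", con)
  vals <- unlist(lapply(model@params$.order,
                        function(nm) as.numeric(get(nm, envir = model@params))))
  writeLines(format(vals, digits = 17, scientific = TRUE, trim = TRUE), con)
  invisible(path)
}

#' Load a checkpoint written by \code{\link{saveCheckpoint}}
#'
#' @param path checkpoint file
#' @return a \linkS4class{SegModel}
#' @export
loadCheckpoint <- function(path) {
  lines <- readLines(path)
  sep <- match("---values---", lines)
  hdr <- yaml::yaml.load(paste(lines[2:(sep - 1)], collapse = "\n"))
  cfg <- ModelConfig(variant = hdr$config$variant,
                     inputShape = unlist(hdr$config$inputShape),
                     inChannels = hdr$config$inChannels,
                     levelWidths = unlist(hdr$config$levelWidths),
                     poolFactors = hdr$config$poolFactors,
                     reductionRatio = hdr$config$reductionRatio,
                     excitation = hdr$config$excitation,
                     seed = hdr$config$seed)
  model <- buildModel(cfg)
  vals <- as.numeric(lines[(sep + 1):length(lines)])
  pos <- 0L
  for (nm in model@params$.order) {
    sh <- unlist(hdr$shapes[[nm]])
    n <- prod(sh)
    v <- vals[pos + seq_len(n)]
    if (length(sh) > 1L) dim(v) <- sh
    assign(nm, v, envir = model@params)
    pos <- pos + n
  }
  stopifnot(pos == length(vals))
  model
}
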