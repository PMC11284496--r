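# Network assembly: the ablation ladder is built from shared encoder /
# decoder stages plus the attention blocks, on top of the autograd tape.
#
# The two backbone families differ in convolutions per stage (one for the
# baseline family -- "a single convolution operation rather than two" -- and
# two for the U-Net family). Skip paths carry nothing, SE, or chained MSSE
# blocks; decoder merges are plain concatenation, an attention gate on the
# skip, or an MSAG gating the decoder features. MSAG variants drop one
# decoder convolution per level (floored at one), which is where the
# parameter saving of the multi-scale gate comes from.

variantTraits <- function(variant) {
  fam <- if (grepl("^unet3d|^attention", variant)) "unet" else "single"
  skip <- if (grepl("MSSE", variant)) "msse"
          else if (grepl("SE", variant)) "se" else "none"
  merge <- if (grepl("MSAG", variant) || variant == "prolesa") "msag"
           else if (grepl("AG", variant) || variant == "attention_unet3d") "ag"
           else "concat"
  if (variant == "prolesa") skip <- "msse"
  cps <- if (fam == "unet") 2L else 1L
  list(family = fam, convsPerStage = cps, skip = skip, merge = merge,
       decConvs = max(cps - (merge == "msag"), 1L))
}

psNew <- function() {
  ps <- new.env(parent = emptyenv())
  ps$.order <- character()
  ps
}

psAdd <- function(ps, name, value) {
  assign(name, value, envir = ps)
  ps$.order <- c(ps$.order, name)
  invisible(NULL)
}

psAddGroup <- function(ps, prefix, lst) {
  for (nm in names(lst)) psAdd(ps, paste0(prefix, ".", nm), lst[[nm]])
}

psGroup <- function(pn, prefix) {
  nms <- grep(paste0("^", gsub("([.+])", "\\\\\\1", prefix), "\\."),
              names(pn), value = TRUE)
  out <- pn[nms]
  names(out) <- sub(paste0("^", gsub("([.+])", "\\\\\\1", prefix), "\\."), "",
                    nms)
  out
}

# pooling factors are configured (z, y, x); kernels run on (C, X, Y, Z)
factorXYZ <- function(f) rev(as.integer(f))

#' Build a segmentation network
#'
#' Assembles the architecture selected by \code{cfg@variant} and
#' initialises all weights (He initialisation for convolutions, partial
#' identity for the kernel-1 "identity" convolutions of MSSE/MSAG, unit
#' gain / zero shift for instance norm) under the configuration seed.
#'
#' @param cfg a \linkS4class{ModelConfig}
#' @return a \linkS4class{SegModel}
#' @examples
#' cfg <- ModelConfig("prolesa", inputShape = c(8L, 32L, 32L),
#'                    levelWidths = c(8L, 16L),
#'                    poolFactors = list(c(2L, 2L, 2L)))
#' countParameters(buildModel(cfg))
#' @export
buildModel <- function(cfg) {
  validObject(cfg)
  tr <- variantTraits(cfg@variant)
  v <- cfg@levelWidths
  L <- length(v)
  r <- cfg@reductionRatio
  ps <- psNew()
  withSeed(cfg@seed, {
    cin <- cfg@inChannels
    for (i in seq_len(L)) {
      for (j in seq_len(tr$convsPerStage)) {
        ci <- if (j == 1L) cin else v[i]
        psAdd(ps, sprintf("enc%d.conv%d.W", i, j), heMatrix(v[i], ci * 27L, ci * 27L))
        psAdd(ps, sprintf("enc%d.conv%d.b", i, j), numeric(v[i]))
        psAdd(ps, sprintf("enc%d.in%d.g", i, j), rep(1, v[i]))
        psAdd(ps, sprintf("enc%d.in%d.b", i, j), numeric(v[i]))
      }
      cin <- v[i]
    }
    if (L > 1L) {
      if (tr$skip == "se")
        for (i in seq_len(L - 1L))
          psAddGroup(ps, sprintf("skip%d", i), initSeWeights(v[i], r))
      if (tr$skip == "msse") {
        psAddGroup(ps, "skip1", initSeWeights(v[1], r))
        if (L > 2L)
          for (i in 2:(L - 1L))
            psAddGroup(ps, sprintf("skip%d", i), initMsseWeights(v[i - 1], v[i], r))
      }
      for (i in seq.int(L - 1L, 1L)) {
        K <- prod(cfg@poolFactors[[i]])
        psAdd(ps, sprintf("up%d.W", i), heMatrix(v[i] * K, v[i + 1], v[i + 1]))
        psAdd(ps, sprintf("up%d.b", i), numeric(v[i]))
        if (tr$merge == "ag")
          psAddGroup(ps, sprintf("gate%d", i), initAgWeights(v[i], v[i]))
        if (tr$merge == "msag")
          psAddGroup(ps, sprintf("gate%d", i), initMsagWeights(v[i], v[i]))
        dcin <- if (tr$merge == "msag") v[i] else 2L * v[i]
        for (j in seq_len(tr$decConvs)) {
          ci <- if (j == 1L) dcin else v[i]
          psAdd(ps, sprintf("dec%d.conv%d.W", i, j), heMatrix(v[i], ci * 27L, ci * 27L))
          psAdd(ps, sprintf("dec%d.conv%d.b", i, j), numeric(v[i]))
          psAdd(ps, sprintf("dec%d.in%d.g", i, j), rep(1, v[i]))
          psAdd(ps, sprintf("dec%d.in%d.b", i, j), numeric(v[i]))
        }
      }
    }
    psAdd(ps, "head.W", heMatrix(1L, v[1], v[1]))
    # head bias starts at the log-odds of a ~1% foreground prior so the
    # untrained net predicts background, which stabilises Dice-based losses
    # on sparse lesions
    psAdd(ps, "head.b", log(0.01 / 0.99))
  })
  new("SegModel", config = cfg, params = ps)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (all convolution and dense weights,
#' biases, and instance-norm gains/shifts). The count is a deterministic
#' function of the \linkS4class{ModelConfig} -- independent of seed and
#' batch size. The calibrated default widths reproduce the published counts:
#' 16,544,129 for \code{prolesa} and 18,335,585 for \code{unet3d}.
#'
#' @param model a \linkS4class{SegModel}
#' @return integer-valued numeric
#' @export
countParameters <- function(model) {
  sum(vapply(model@params$.order,
             function(nm) length(get(nm, envir = model@params)), numeric(1)))
}

#' Per-layer parameter table
#'
#' @param model a \linkS4class{SegModel}
#' @return data.frame with columns parameter, shape, count
#' @export
layerSummary <- function(model) {
  nms <- model@params$.order
  data.frame(
    parameter = nms,
    shape = vapply(nms, function(nm) {
      d <- dim(get(nm, envir = model@params))
      if (is.null(d)) as.character(length(get(nm, envir = model@params)))
      else paste(d, collapse = "x")
    }, character(1)),
    count = vapply(nms, function(nm) length(get(nm, envir = model@params)),
                   numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

bindParams <- function(tape, model) {
  nms <- model@params$.order
  pn <- lapply(nms, function(nm) ag_leaf(tape, get(nm, envir = model@params)))
  names(pn) <- nms
  pn
}

# Build the forward graph on the tape; x is a node with value (C, X, Y, Z).
# Returns list(z = logits node (1, X, Y, Z), p = probability node).
modelGraph <- function(tape, model, pn, x) {
  cfg <- model@config
  tr <- variantTraits(cfg@variant)
  v <- cfg@levelWidths
  L <- length(v)
  convInRelu <- function(nd, prefix, j) {
    nd <- ag_conv3d(tape, nd, pn[[sprintf("%s.conv%d.W", prefix, j)]],
                    pn[[sprintf("%s.conv%d.b", prefix, j)]],
                    c(3L, 3L, 3L), c(1L, 1L, 1L), c(1L, 1L, 1L))
    nd <- ag_instnorm(tape, nd, pn[[sprintf("%s.in%d.g", prefix, j)]],
                      pn[[sprintf("%s.in%d.b", prefix, j)]])
    ag_relu(tape, nd)
  }
  e <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    if (i > 1L) cur <- ag_maxpool(tape, cur, factorXYZ(cfg@poolFactors[[i - 1]]))
    for (j in seq_len(tr$convsPerStage))
      cur <- convInRelu(cur, sprintf("enc%d", i), j)
    e[[i]] <- cur
  }
  d <- e[[L]]
  if (L > 1L) {
    s <- vector("list", L - 1L)
    for (i in seq_len(L - 1L)) {
      s[[i]] <- switch(tr$skip,
        none = e[[i]],
        se = agSeBlock(tape, e[[i]], psGroup(pn, sprintf("skip%d", i))),
        msse = if (i == 1L)
          agSeBlock(tape, e[[1]], psGroup(pn, "skip1"))
        else
          agMsseBlock(tape, s[[i - 1]], e[[i]],
                      psGroup(pn, sprintf("skip%d", i)),
                      stride = factorXYZ(cfg@poolFactors[[i - 1]]),
                      excitation = cfg@excitation))
    }
    for (i in seq.int(L - 1L, 1L)) {
      u <- ag_relu(tape, ag_convt3d(tape, d, pn[[sprintf("up%d.W", i)]],
                                    pn[[sprintf("up%d.b", i)]],
                                    factorXYZ(cfg@poolFactors[[i]])))
      m <- switch(tr$merge,
        concat = ag_concat_channels(tape, s[[i]], u),
        ag = {
          gt <- agAttentionGate(tape, u, s[[i]],
                                psGroup(pn, sprintf("gate%d", i)))
          ag_concat_channels(tape, gt$out, u)
        },
        msag = agMsagBlock(tape, s[[i]], u,
                           psGroup(pn, sprintf("gate%d", i)))$out)
      for (j in seq_len(tr$decConvs))
        m <- convInRelu(m, sprintf("dec%d", i), j)
      d <- m
    }
  }
  z <- ag_conv3d(tape, d, pn[["head.W"]], pn[["head.b"]],
                 c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  list(z = z, p = ag_sigmoid(tape, z))
}

checkInputShape <- function(model, d) {
  want <- c(model@config@inputShape, model@config@inChannels)
  if (!identical(as.integer(d), as.integer(want)))
    stop(sprintf("input shape (%s) does not match the model input (%s)",
                 paste(d, collapse = "x"), paste(want, collapse = "x")))
}

#' Run a forward pass
#'
#' Maps an input tensor to voxelwise lesion probabilities (sigmoid head, so
#' values lie in [0, 1]).
#'
#' @param model a \linkS4class{SegModel}
#' @param x numeric array, either (depth, height, width, channels) or a
#'   batch (batch, depth, height, width, channels)
#' @return probabilities: (depth, height, width) for a single input, or
#'   (batch, depth, height, width, 1) for a batch
#' @export
modelForward <- function(model, x) {
  nd <- length(dim(x))
  if (nd == 5L) {
    B <- dim(x)[1]
    out <- array(0, c(B, dim(x)[2:4], 1L))
    for (b in seq_len(B))
      out[b, , , , 1] <- modelForward(model, array(x[b, , , , ], dim(x)[-1]))
    return(out)
  }
  checkInputShape(model, dim(x))
  tape <- ag_tape()
  pn <- bindParams(tape, model)
  xn <- ag_leaf(tape, aperm(x, c(4, 3, 2, 1)))
  g <- modelGraph(tape, model, pn, xn)
  p <- g$p$value
  aperm(array(p, dim(p)[-1]), c(3, 2, 1))
}

#' Predict a binary lesion mask for one case
#'
#' Thresholds the sigmoid output at \code{threshold} (inclusive: a voxel at
#' exactly the threshold is foreground). No connected-component
#' postprocessing is applied.
#'
#' @param model a \linkS4class{SegModel}
#' @param input a \linkS4class{ModelInput}
#' @param threshold probability cutoff, default 0.5
#' @return binary \linkS4class{ImageVolume} on the input grid
#' @export
predictCase <- function(model, input, threshold = 0.5) {
  prob <- modelForward(model, input@tensor)
  ImageVolume(array(as.numeric(prob >= threshold), dim(prob)),
              input@spacing, mask = TRUE)
}
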