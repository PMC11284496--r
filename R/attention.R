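# User-facing attention blocks. These operate on plain (batch, depth,
# height, width, channels) arrays so the mechanisms can be studied and
# tested in isolation; inside a network the same graph builders are used.

asInternal <- function(x) aperm(x, c(4, 3, 2, 1))   # (D,H,W,C) -> (C,X,Y,Z)
asExternal <- function(x) aperm(x, c(4, 3, 2, 1))   # inverse permutation

batchApply <- function(x, fn) {
  d <- dim(x)
  if (length(d) == 4L) return(fn(x))
  out <- NULL
  for (b in seq_len(d[1])) {
    r <- fn(array(x[b, , , , ], d[-1]))
    if (is.null(out)) out <- array(0, c(d[1], dim(r)))
    out[b, , , , ] <- r
  }
  out
}

bindWeights <- function(tape, w) lapply(w, function(v) ag_leaf(tape, v))

#' Create weights for a stand-alone attention block
#'
#' Returns the named list of weight arrays a block function expects, with
#' seeded initialisation (He for dense/pointwise layers, partial identity
#' for the kernel-1 "identity" convolutions). All entries are plain
#' numeric matrices/vectors and can be frozen or edited for closed-form
#' checks.
#'
#' @param type one of \code{"se"}, \code{"ag"}, \code{"msse"}, \code{"msag"}
#' @param channels channel count the block operates on (the low-resolution
#'   / skip channel count for \code{msse} / \code{msag})
#' @param inChannels second channel count where applicable: the
#'   high-resolution residual channels for \code{msse}, the gating-signal
#'   channels for \code{ag}, the encoder-skip channels for \code{msag};
#'   defaults to \code{channels}
#' @param reductionRatio squeeze reduction ratio r (default 8)
#' @param seed RNG seed
#' @return named list of weight arrays
#' @export
attentionWeights <- function(type = c("se", "ag", "msse", "msag"),
                             channels, inChannels = channels,
                             reductionRatio = 8L, seed = 1L) {
  type <- match.arg(type)
  withSeed(seed, switch(type,
    se = initSeWeights(channels, reductionRatio),
    ag = initAgWeights(inChannels, channels),
    msse = initMsseWeights(inChannels, channels, reductionRatio),
    msag = initMsagWeights(inChannels, channels)))
}

#' Squeeze-and-excitation block
#'
#' Channel attention: per-channel scores
#' \code{sigmoid(FC2(ReLU(FC1(GAP(x)))))} rescale the input channels.
#' Scores lie in (0, 1), so no activation ever grows in magnitude.
#'
#' @param x numeric array (batch, depth, height, width, channels) or
#'   (depth, height, width, channels)
#' @param weights list from \code{attentionWeights("se", ...)}
#' @param reductionRatio squeeze ratio used when \code{weights} is NULL
#' @param seed seed used when \code{weights} is NULL
#' @return array of the same shape as \code{x}
#' @export
seBlock <- function(x, weights = NULL, reductionRatio = 8L, seed = 1L) {
  C <- dim(x)[length(dim(x))]
  if (C < reductionRatio && is.null(weights))
    stop(sprintf("channel count %d is smaller than the reduction ratio %d",
                 C, reductionRatio))
  if (is.null(weights))
    weights <- attentionWeights("se", C, reductionRatio = reductionRatio,
                                seed = seed)
  batchApply(x, function(xi) {
    tape <- ag_tape()
    out <- agSeBlock(tape, ag_leaf(tape, asInternal(xi)),
                     bindWeights(tape, weights))
    asExternal(out$value)
  })
}

#' Additive attention gate
#'
#' Spatial attention on a skip connection: a single-channel coefficient map
#' \code{alpha = sigmoid(psi(ReLU(Wg g + Ws s)))} multiplies the skip
#' features \code{s}. The returned array carries \code{alpha} (shape
#' (..., 1)) as attribute \code{"alpha"}.
#'
#' @param g gating signal array, same grid as \code{s}
#' @param s skip feature array (batch, depth, height, width, channels)
#' @param weights list from \code{attentionWeights("ag", ...)}
#' @param interChannels intermediate width used when \code{weights} is NULL
#' @param seed seed used when \code{weights} is NULL
#' @return gated array, shape of \code{s}, with attribute \code{"alpha"}
#' @export
attentionGate <- function(g, s, weights = NULL, interChannels = NULL,
                          seed = 1L) {
  dg <- dim(g); ds <- dim(s)
  if (!identical(dg[-length(dg)], ds[-length(ds)]))
    stop("gating signal and skip features must share one spatial grid")
  Cg <- dg[length(dg)]; Cs <- ds[length(ds)]
  if (is.null(weights)) {
    inter <- if (is.null(interChannels)) max(1L, Cs %/% 2L) else interChannels
    weights <- withSeed(seed, initAgWeights(Cg, Cs, inter))
  }
  alphas <- NULL
  run1 <- function(gi, si) {
    tape <- ag_tape()
    res <- agAttentionGate(tape, ag_leaf(tape, asInternal(gi)),
                           ag_leaf(tape, asInternal(si)),
                           bindWeights(tape, weights))
    list(out = asExternal(res$out$value), alpha = asExternal(res$alpha$value))
  }
  if (length(dg) == 4L) {
    r <- run1(g, s)
    return(structure(r$out, alpha = r$alpha))
  }
  out <- array(0, ds)
  alphas <- array(0, c(dg[1:4], 1L))
  for (b in seq_len(dg[1])) {
    r <- run1(array(g[b, , , , ], dg[-1]), array(s[b, , , , ], ds[-1]))
    out[b, , , , ] <- r$out
    alphas[b, , , , ] <- r$alpha
  }
  structure(out, alpha = alphas)
}

#' Multi-scale squeeze-and-excitation block
#'
#' Fuses the high-resolution residual from the previous encoder level with
#' the current low-resolution residual before channel recalibration: a
#' kernel-1 convolution with the pooling stride brings \code{hrr} to the
#' coarse grid and channel count, the fused map \code{FMA = HRR + lrr} is
#' globally average-pooled, passed through the excitation pair
#' (C -> C/r -> C), and the resulting per-channel scores rescale
#' \code{FMA}. The default excitation ends in ReLU; set
#' \code{excitation = "sigmoid"} for the classic bounded SE scores.
#'
#' @param hrr high-resolution residual (..., D, H, W, Ch), spatial dims a
#'   stride multiple of \code{lrr}'s
#' @param lrr low-resolution residual (..., d, h, w, Cl)
#' @param weights list from \code{attentionWeights("msse", ...)}
#' @param stride integer length-3 (z, y, x) downsampling factors, default
#'   (2, 2, 2)
#' @param reductionRatio,seed used when \code{weights} is NULL
#' @param excitation \code{"relu"} (default) or \code{"sigmoid"}
#' @return array with the grid and channels of \code{lrr}
#' @export
msseBlock <- function(hrr, lrr, weights = NULL, stride = c(2L, 2L, 2L),
                      reductionRatio = 8L, seed = 1L, excitation = "relu") {
  dh <- dim(hrr); dl <- dim(lrr)
  Ch <- dh[length(dh)]; Cl <- dl[length(dl)]
  if (is.null(weights))
    weights <- attentionWeights("msse", Cl, Ch, reductionRatio, seed)
  strideXYZ <- rev(as.integer(stride))
  run1 <- function(hi, li) {
    tape <- ag_tape()
    out <- agMsseBlock(tape, ag_leaf(tape, asInternal(hi)),
                       ag_leaf(tape, asInternal(li)),
                       bindWeights(tape, weights), strideXYZ, excitation)
    asExternal(out$value)
  }
  if (length(dh) == 4L) return(run1(hrr, lrr))
  out <- array(0, dl)
  for (b in seq_len(dh[1]))
    out[b, , , , ] <- run1(array(hrr[b, , , , ], dh[-1]),
                           array(lrr[b, , , , ], dl[-1]))
  out
}

#' Multi-scale attention gate
#'
#' Gates decoder features with a spatial attention map built from the
#' encoder skip: pointwise convolutions homogenise both inputs to the
#' decoder channel count and are summed (\code{FMA}); a per-channel spatial
#' softmax of \code{FMA * FPR} is condensed to a single channel by a
#' pointwise convolution and squashed by a sigmoid; the resulting gate in
#' (0, 1) multiplies the decoder features. The output carries the softmax
#' map (attribute \code{"softmax"}) and the single-channel gate (attribute
#' \code{"gate"}).
#'
#' @param seOut encoder-side features (skip / MSSE output), same grid as
#'   \code{fpr}
#' @param fpr decoder features to be gated
#' @param weights list from \code{attentionWeights("msag", ...)}
#' @param seed used when \code{weights} is NULL
#' @return gated array, shape of \code{fpr}
#' @export
msagBlock <- function(seOut, fpr, weights = NULL, seed = 1L) {
  ds <- dim(seOut); df <- dim(fpr)
  Cs <- ds[length(ds)]; Cf <- df[length(df)]
  if (is.null(weights)) weights <- attentionWeights("msag", Cf, Cs, seed = seed)
  run1 <- function(si, fi) {
    tape <- ag_tape()
    res <- agMsagBlock(tape, ag_leaf(tape, asInternal(si)),
                       ag_leaf(tape, asInternal(fi)),
                       bindWeights(tape, weights))
    list(out = asExternal(res$out$value),
         softmax = asExternal(res$softmax$value),
         gate = asExternal(res$gate$value))
  }
  if (length(ds) == 4L) {
    r <- run1(seOut, fpr)
    return(structure(r$out, softmax = r$softmax, gate = r$gate))
  }
  out <- array(0, df)
  sm <- array(0, df)
  gt <- array(0, c(df[1:4], 1L))
  for (b in seq_len(ds[1])) {
    r <- run1(array(seOut[b, , , , ], ds[-1]), array(fpr[b, , , , ], df[-1]))
    out[b, , , , ] <- r$out
    sm[b, , , , ] <- r$softmax
    gt[b, , , , ] <- r$gate
  }
  structure(out, softmax = sm, gate = gt)
}
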