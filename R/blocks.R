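# Internal graph builders for the four attention blocks. These are shared
# between the exported array-level block functions (attention.R) and the
# network assembly (model.R), so the equations are implemented exactly once.
#
# All builders take tape nodes with values in the internal (C, X, Y, Z)
# layout; weight entries are nodes created from the weight lists documented
# in attentionWeights().

spatialDims <- function(nd) dim(nd$value)[-1]

# squeeze-and-excitation: x * sigmoid(FC2(ReLU(FC1(GAP(x)))))
agSeBlock <- function(tape, x, w) {
  C <- dim(x$value)[1]
  if (C < nrow(w$fc1W$value))
    stop("se_block: channel count is smaller than the squeeze width")
  g <- ag_gap(tape, x)
  h <- ag_relu(tape, ag_dense(tape, g, w$fc1W, w$fc1b))
  s <- ag_sigmoid(tape, ag_dense(tape, h, w$fc2W, w$fc2b))
  ag_scale_channels(tape, x, s)
}

# additive attention gate: alpha = sigmoid(psi(ReLU(Wg g + Ws s))),
# out = alpha * s; alpha has a single channel
agAttentionGate <- function(tape, g, s, w) {
  if (!identical(spatialDims(g), spatialDims(s)))
    stop("attention_gate: gating signal and skip features must share one grid")
  q1 <- ag_conv3d(tape, g, w$wgW, w$wgb, c(1L, 1L, 1L), c(1L, 1L, 1L),
                  c(0L, 0L, 0L))
  q2 <- ag_conv3d(tape, s, w$wsW, w$wsb, c(1L, 1L, 1L), c(1L, 1L, 1L),
                  c(0L, 0L, 0L))
  alpha <- ag_sigmoid(tape, ag_conv3d(tape, ag_relu(tape, ag_add(tape, q1, q2)),
                                      w$psiW, w$psib, c(1L, 1L, 1L),
                                      c(1L, 1L, 1L), c(0L, 0L, 0L)))
  list(out = ag_mul_single(tape, s, alpha), alpha = alpha)
}

# multi-scale squeeze-and-excitation:
# (1) the high-resolution residual is brought to the coarse grid and to the
#     low-resolution channel count by a kernel-1 strided conv;
# (2) FMA = HRR + lrr elementwise;
# (3) GAP over all spatial positions;
# (4) excitation FC pair (C -> C/r -> C), ReLU after both layers by default
#     (a sigmoid option restores the classic SE ending);
# SEout = FMA scaled per channel by the excitation scores.
agMsseBlock <- function(tape, hrr, lrr, w, stride, excitation = "relu") {
  dh <- spatialDims(hrr); dl <- spatialDims(lrr)
  if (!identical(as.integer(dh), as.integer(dl * stride)))
    stop(sprintf(paste0("msse_block: high-resolution grid (%s) is not the ",
                        "stride multiple (%s) of the low-resolution grid (%s)"),
                 paste(dh, collapse = "x"), paste(stride, collapse = "x"),
                 paste(dl, collapse = "x")))
  HRR <- ag_conv3d(tape, hrr, w$downW, w$downb, c(1L, 1L, 1L),
                   as.integer(stride), c(0L, 0L, 0L))
  FMA <- ag_add(tape, HRR, lrr)
  g <- ag_gap(tape, FMA)
  h <- ag_relu(tape, ag_dense(tape, g, w$fc1W, w$fc1b))
  s <- ag_dense(tape, h, w$fc2W, w$fc2b)
  s <- if (excitation == "sigmoid") ag_sigmoid(tape, s) else ag_relu(tape, s)
  ag_scale_channels(tape, FMA, s)
}

# multi-scale attention gate:
# (1) pointwise convs homogenise the encoder skip (SEout) and the decoder
#     features (FPR) to the FPR channel count; their sum is FMA;
# (2) A = spatial softmax (per channel) of FMA * FPR;
# (3) SigmOut = sigmoid(pointwise conv of A to one channel);
# out = SigmOut * FPR broadcast over channels.
agMsagBlock <- function(tape, se, fpr, w) {
  if (!identical(spatialDims(se), spatialDims(fpr)))
    stop("msag_block: encoder and decoder features must share one grid")
  c1 <- ag_conv3d(tape, se, w$seW, w$seb, c(1L, 1L, 1L), c(1L, 1L, 1L),
                  c(0L, 0L, 0L))
  c2 <- ag_conv3d(tape, fpr, w$fprW, w$fprb, c(1L, 1L, 1L), c(1L, 1L, 1L),
                  c(0L, 0L, 0L))
  FMA <- ag_add(tape, c1, c2)
  A <- ag_softmax_spatial(tape, ag_mul(tape, FMA, fpr))
  gate <- ag_sigmoid(tape, ag_conv3d(tape, A, w$outW, w$outb, c(1L, 1L, 1L),
                                     c(1L, 1L, 1L), c(0L, 0L, 0L)))
  list(out = ag_mul_single(tape, fpr, gate), softmax = A, gate = gate)
}

## ---- weight initialisers ----

heMatrix <- function(nrow, ncol, fanIn) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fanIn)), nrow, ncol)
}

# kernel-1 "identity" convolution: learnable, initialised to a (partial)
# identity mapping plus small noise so it starts as a pass-through where
# channel counts allow
identityPointwise <- function(cin, cout) {
  w <- matrix(stats::rnorm(cout * cin, sd = 0.01), cout, cin)
  k <- min(cin, cout)
  w[cbind(seq_len(k), seq_len(k))] <- w[cbind(seq_len(k), seq_len(k))] + 1
  w
}

squeezeWidth <- function(C, r) max(1L, C %/% as.integer(r))

initSeWeights <- function(C, r = 8L) {
  f <- squeezeWidth(C, r)
  list(fc1W = heMatrix(f, C, C), fc1b = numeric(f),
       fc2W = heMatrix(C, f, f), fc2b = numeric(C))
}

initAgWeights <- function(Cg, Cs, inter = max(1L, Cs %/% 2L)) {
  list(wgW = heMatrix(inter, Cg, Cg), wgb = numeric(inter),
       wsW = heMatrix(inter, Cs, Cs), wsb = numeric(inter),
       psiW = heMatrix(1L, inter, inter), psib = numeric(1))
}

initMsseWeights <- function(Ch, Cl, r = 8L) {
  f <- squeezeWidth(Cl, r)
  list(downW = identityPointwise(Ch, Cl), downb = numeric(Cl),
       fc1W = heMatrix(f, Cl, Cl), fc1b = numeric(f),
       fc2W = heMatrix(Cl, f, f), fc2b = numeric(Cl))
}

initMsagWeights <- function(Cs, Cf) {
  list(seW = identityPointwise(Cs, Cf), seb = numeric(Cf),
       fprW = identityPointwise(Cf, Cf), fprb = numeric(Cf),
       outW = heMatrix(1L, Cf, Cf), outb = numeric(1))
}
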