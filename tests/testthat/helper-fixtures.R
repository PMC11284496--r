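# Shared fixtures: everything is generated in code at test time.

# small phantom spec that keeps preprocessing fast
tinySpec <- function(seed = 1L, diameter = 12, noise = 0, ...) {
  PhantomSpec(gridShape = c(12L, 72L, 72L), spacingMM = c(3, 1, 1),
              glandSemiaxesMM = c(14, 22, 24), lesionDiametersMM = diameter,
              noiseSigma = noise, seed = seed, ...)
}

tinyPreprocess <- function() {
  PreprocessConfig(targetSpacingMM = c(3, 1, 1),
                   targetShape = c(16L, 64L, 64L))
}

# 3-level toy network configuration on a 8x32x32 grid
toyModelConfig <- function(variant = "prolesa", seed = 1L,
                           widths = c(8L, 16L, 32L),
                           shape = c(8L, 32L, 32L)) {
  ModelConfig(variant, inputShape = shape, levelWidths = widths,
              poolFactors = rep(list(c(2L, 2L, 2L)), length(widths) - 1L),
              seed = seed)
}

# reduced geometry of the overfit smoke runs
smokeGeometry <- function() {
  list(spec = PhantomSpec(gridShape = c(12L, 72L, 72L), spacingMM = c(3, 1, 1),
                          glandSemiaxesMM = c(14, 22, 24),
                          lesionDiametersMM = 14, noiseSigma = 0, seed = 11L),
       prep = PreprocessConfig(targetSpacingMM = c(3, 1, 1),
                               targetShape = c(16L, 64L, 64L)),
       widths = c(8L, 16L, 32L),
       pools = list(c(2L, 2L, 2L), c(2L, 2L, 2L)))
}

# random binary mask on a small grid
randomMask <- function(dim3, p = 0.15) {
  array(as.numeric(stats::runif(prod(dim3)) < p), dim3)
}

# brute-force surface distances: all pairs of surface voxel centres,
# squared differences taken directly (no norm expansion, which would lose
# ~1e-9 to cancellation)
bruteSurfaceStats <- function(gt, pr, spacing) {
  a <- surfaceVoxels(gt, spacing)
  b <- surfaceVoxels(pr, spacing)
  if (nrow(a) == 0 && nrow(b) == 0) return(list(hd = 0, asd = 0))
  if (nrow(a) == 0 || nrow(b) == 0) return(list(hd = Inf, asd = Inf))
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2 +
    outer(a[, 3], b[, 3], `-`)^2
  d <- sqrt(d2)
  dab <- apply(d, 1, min)
  dba <- apply(d, 2, min)
  list(hd = max(max(dab), max(dba)),
       asd = (sum(dab) + sum(dba)) / (length(dab) + length(dba)))
}

# finite-difference gradient of f at x, at a sample of entries
fdGrad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, numeric(1))
}
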