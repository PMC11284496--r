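# Closed-form and property checks for the four attention blocks.

zeroSeWeights <- function(C, r = 8L) {
  f <- max(1L, C %/% r)
  list(fc1W = matrix(0, f, C), fc1b = numeric(f),
       fc2W = matrix(0, C, f), fc2b = numeric(C))
}

test_that("SE block reduces to 0.5-scaling under frozen zero weights", {
  C <- 16L
  x <- array(3, c(2, 4, 4, C)) # constant batch of 2
  out <- seBlock(x, weights = zeroSeWeights(C))
  expect_equal(out, x * 0.5, tolerance = 1e-12)
  z <- seBlock(array(0, c(4, 4, 4, C)), weights = zeroSeWeights(C))
  expect_true(all(z == 0))
  set.seed(1)
  xr <- array(stats::rnorm(4 * 4 * 4 * C), c(4, 4, 4, C))
  outr <- seBlock(xr, seed = 5L)
  expect_true(all(abs(outr) <= abs(xr) + 1e-12)) # sigmoid scores < 1
  expect_error(seBlock(array(0, c(2, 2, 2, 4)), reductionRatio = 8L),
               "smaller than the reduction ratio")
})

test_that("attention gate produces a single-channel bounded coefficient map", {
  C <- 6L
  set.seed(2)
  g <- array(stats::rnorm(3 * 4 * 4 * C), c(3, 4, 4, C))
  s <- array(stats::rnorm(3 * 4 * 4 * C), c(3, 4, 4, C))
  out <- attentionGate(g, s, seed = 4L)
  al <- attr(out, "alpha")
  expect_identical(dim(al), c(3L, 4L, 4L, 1L))
  expect_true(all(al > 0 & al < 1))
  expect_true(all(abs(out) <= abs(s) + 1e-12))
  zw <- list(wgW = matrix(0, 3, C), wgb = numeric(3),
             wsW = matrix(0, 3, C), wsb = numeric(3),
             psiW = matrix(0, 1, 3), psib = numeric(1))
  out0 <- attentionGate(g, s, weights = zw)
  expect_equal(out0, s * 0.5, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(attentionGate(g, s * 0, seed = 1L) == 0))
  expect_error(attentionGate(array(0, c(2, 4, 4, C)), s), "grid")
})

test_that("MSSE matches its shape contract and identity-score limit", {
  set.seed(3)
  hrr <- array(stats::rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  lrr <- array(stats::rnorm(4 * 4 * 4 * 8), c(4, 4, 4, 8))
  out <- msseBlock(hrr, lrr, seed = 2L)
  expect_identical(dim(out), dim(lrr))
  expect_true(all(msseBlock(hrr * 0, lrr * 0, seed = 2L) == 0))
  # frozen weights with zero FC1 and unit FC2 bias give scores exactly 1,
  # so SEout equals the aggregated map FMA; with a zero down-conv FMA = lrr
  w <- list(downW = matrix(0, 8, 4), downb = numeric(8),
            fc1W = matrix(0, 1, 8), fc1b = numeric(1),
            fc2W = matrix(0, 8, 1), fc2b = rep(1, 8))
  expect_equal(msseBlock(hrr, lrr, weights = w), lrr, tolerance = 1e-12)
  # anisotropic stride: only pooled axes shrink
  h2 <- array(stats::rnorm(6 * 8 * 8 * 4), c(6, 8, 8, 4))
  l2 <- array(stats::rnorm(6 * 4 * 4 * 8), c(6, 4, 4, 8))
  expect_identical(dim(msseBlock(h2, l2, stride = c(1L, 2L, 2L), seed = 1L)),
                   dim(l2))
  expect_error(msseBlock(hrr, array(0, c(3, 4, 4, 8)), seed = 1L),
               "stride multiple")
})

test_that("MSSE is equivariant under a joint channel permutation", {
  set.seed(4)
  Ch <- 4L; Cl <- 8L
  hrr <- array(stats::rnorm(4 * 4 * 4 * Ch), c(4, 4, 4, Ch))
  lrr <- array(stats::rnorm(2 * 2 * 2 * Cl), c(2, 2, 2, Cl))
  w <- attentionWeights("msse", Cl, Ch, seed = 9L)
  out <- msseBlock(hrr, lrr, weights = w)
  pi_l <- sample(Cl); pi_h <- sample(Ch)
  wp <- list(downW = w$downW[pi_l, pi_h], downb = w$downb[pi_l],
             fc1W = w$fc1W[, pi_l, drop = FALSE], fc1b = w$fc1b,
             fc2W = w$fc2W[pi_l, , drop = FALSE], fc2b = w$fc2b[pi_l])
  outp <- msseBlock(hrr[, , , pi_h, drop = FALSE],
                    lrr[, , , pi_l, drop = FALSE], weights = wp)
  expect_equal(outp, out[, , , pi_l, drop = FALSE], tolerance = 1e-10)
})

test_that("MSAG softmax conserves mass and the gate bounds activations", {
  set.seed(5)
  C <- 6L
  se <- array(stats::rnorm(4 * 6 * 6 * C), c(4, 6, 6, C))
  fpr <- array(stats::rnorm(4 * 6 * 6 * C), c(4, 6, 6, C))
  out <- msagBlock(se, fpr, seed = 3L)
  A <- attr(out, "softmax")
  sums <- apply(A, 4, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  gate <- attr(out, "gate")
  expect_identical(dim(gate), c(4L, 6L, 6L, 1L))
  expect_true(all(gate > 0 & gate < 1))
  expect_true(all(abs(out) <= abs(fpr) + 1e-12))
  expect_true(all(msagBlock(se, fpr * 0, seed = 3L) == 0))
  # saturating the single-channel conv towards -Inf shuts the gate
  w <- attentionWeights("msag", C, C, seed = 3L)
  w$outb <- -60
  out0 <- msagBlock(se, fpr, weights = w)
  expect_lt(max(abs(out0)), 1e-12)
  expect_error(msagBlock(array(0, c(2, 6, 6, C)), fpr, seed = 1L), "grid")
})

test_that("global average pooling equals the brute-force spatial mean", {
  set.seed(6)
  for (trial in 1:5) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(2:4, 1), sample(2:3, 1))
    x <- array(stats::rnorm(prod(d)), d) # internal (C, X, Y, Z)
    tape <- prolesaNet:::ag_tape()
    g <- prolesaNet:::ag_gap(tape, prolesaNet:::ag_leaf(tape, x))
    brute <- vapply(seq_len(d[1]), function(c) mean(x[c, , , ]), numeric(1))
    expect_equal(g$value, brute, tolerance = 1e-6)
  }
})
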