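# Finite-difference checks of every tape operation the networks use.
# Each op is exercised through a scalar objective sum(out * R) whose
# gradient the tape must reproduce at sampled entries.

agCheck <- function(buildFn, x, n = 12, tol = 1e-5) {
  set.seed(99)
  probe <- NULL
  runval <- function(xv) {
    tape <- prolesaNet:::ag_tape()
    out <- buildFn(tape, prolesaNet:::ag_leaf(tape, xv))
    if (is.null(probe))
      probe <<- array(stats::rnorm(length(out$value)),
                      dim(out$value) %||% length(out$value))
    sum(out$value * probe)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  runval(x) # fixes the probe
  tape <- prolesaNet:::ag_tape()
  xn <- prolesaNet:::ag_leaf(tape, x)
  out <- buildFn(tape, xn)
  loss <- prolesaNet:::ag_node(tape, sum(out$value * probe), list(out),
                               function(g) list(g * probe))
  prolesaNet:::ag_backward(tape, loss)
  idx <- sample(length(x), min(n, length(x)))
  expect_equal(as.numeric(xn$grad[idx]), fdGrad(runval, x, idx),
               tolerance = tol)
}

test_that("convolution gradients match finite differences", {
  set.seed(7)
  x <- array(stats::rnorm(3 * 6 * 5 * 4), c(3, 6, 5, 4))
  w <- matrix(stats::rnorm(4 * 81), 4, 81)
  b <- stats::rnorm(4)
  agCheck(function(tp, xn)
    prolesaNet:::ag_conv3d(tp, xn, prolesaNet:::ag_leaf(tp, w),
                           prolesaNet:::ag_leaf(tp, b), c(3L, 3L, 3L)), x)
  # kernel-1 stride-2 (the MSSE downsampling path)
  w1 <- matrix(stats::rnorm(2 * 3), 2, 3)
  agCheck(function(tp, xn)
    prolesaNet:::ag_conv3d(tp, xn, prolesaNet:::ag_leaf(tp, w1),
                           prolesaNet:::ag_leaf(tp, numeric(2)),
                           c(1L, 1L, 1L), c(2L, 2L, 2L), c(0L, 0L, 0L)), x)
  # weight gradient of the strided conv
  runw <- function(wv) {
    prolesaNet:::cpp_conv3d_fwd(x, wv, numeric(2), c(1L, 1L, 1L),
                                c(2L, 2L, 2L), c(0L, 0L, 0L))
  }
  probe <- array(stats::rnorm(length(runw(w1))), dim(runw(w1)))
  gw <- prolesaNet:::cpp_conv3d_bwd(x, w1, probe, c(1L, 1L, 1L),
                                    c(2L, 2L, 2L), c(0L, 0L, 0L))$gw
  fd <- fdGrad(function(wv) sum(runw(wv) * probe), w1, seq_along(w1))
  expect_equal(as.numeric(gw), fd, tolerance = 1e-6)
})

test_that("transposed convolution and max-pooling gradients match finite differences", {
  set.seed(8)
  x <- array(stats::rnorm(3 * 4 * 4 * 4), c(3, 4, 4, 4))
  wt <- matrix(stats::rnorm(2 * 8 * 3), 16, 3)
  agCheck(function(tp, xn)
    prolesaNet:::ag_convt3d(tp, xn, prolesaNet:::ag_leaf(tp, wt),
                            prolesaNet:::ag_leaf(tp, numeric(2)),
                            c(2L, 2L, 2L)), x)
  xp <- array(stats::rnorm(2 * 6 * 6 * 4) + seq_len(2 * 6 * 6 * 4) * 1e-3,
              c(2, 6, 6, 4)) # distinct values -> stable argmax
  agCheck(function(tp, xn) prolesaNet:::ag_maxpool(tp, xn, c(2L, 2L, 2L)), xp)
})

test_that("normalisation, pooling and softmax gradients match finite differences", {
  set.seed(9)
  x <- array(stats::rnorm(4 * 5 * 4 * 3), c(4, 5, 4, 3))
  g <- stats::rnorm(4); b <- stats::rnorm(4)
  agCheck(function(tp, xn)
    prolesaNet:::ag_instnorm(tp, xn, prolesaNet:::ag_leaf(tp, g),
                             prolesaNet:::ag_leaf(tp, b)), x, tol = 1e-4)
  agCheck(function(tp, xn) prolesaNet:::ag_gap(tp, xn), x)
  agCheck(function(tp, xn) prolesaNet:::ag_softmax_spatial(tp, xn), x)
  s <- stats::rnorm(4)
  agCheck(function(tp, xn)
    prolesaNet:::ag_scale_channels(tp, xn, prolesaNet:::ag_leaf(tp, s)), x)
  a <- array(stats::rnorm(5 * 4 * 3), c(1, 5, 4, 3))
  agCheck(function(tp, xn)
    prolesaNet:::ag_mul_single(tp, xn, prolesaNet:::ag_leaf(tp, a)), x)
})

test_that("the segmentation loss gradient matches finite differences", {
  set.seed(10)
  z <- array(stats::rnorm(1 * 6 * 6 * 4), c(1, 6, 6, 4))
  y <- array(as.numeric(stats::runif(length(z)) < 0.3), dim(z))
  for (wts in list(c(1, 1), c(1, 0), c(0, 1))) {
    run <- function(zv) {
      tape <- prolesaNet:::ag_tape()
      prolesaNet:::ag_seg_loss(tape, prolesaNet:::ag_leaf(tape, zv), y,
                               w_dice = wts[1], w_bce = wts[2])$value
    }
    tape <- prolesaNet:::ag_tape()
    zn <- prolesaNet:::ag_leaf(tape, z)
    loss <- prolesaNet:::ag_seg_loss(tape, zn, y, w_dice = wts[1],
                                     w_bce = wts[2])
    prolesaNet:::ag_backward(tape, loss)
    idx <- sample(length(z), 10)
    expect_equal(as.numeric(zn$grad[idx]), fdGrad(run, z, idx),
                 tolerance = 1e-5)
  }
})

test_that("a whole-network gradient matches finite differences on a toy build", {
  set.seed(11)
  cfg <- ModelConfig("prolesa", inputShape = c(4L, 8L, 8L),
                     levelWidths = c(8L, 16L),
                     poolFactors = list(c(2L, 2L, 2L)), seed = 3L)
  m <- buildModel(cfg)
  x <- aperm(array(stats::runif(4 * 8 * 8 * 3), c(4, 8, 8, 3)), c(4, 3, 2, 1))
  y <- array(0, c(1, 8, 8, 4)); y[1, 3:5, 3:5, 2:3] <- 1
  lossAt <- function(nm, vv) {
    old <- get(nm, envir = m@params)
    assign(nm, vv, envir = m@params)
    on.exit(assign(nm, old, envir = m@params))
    tape <- prolesaNet:::ag_tape()
    pn <- prolesaNet:::bindParams(tape, m)
    g <- prolesaNet:::modelGraph(tape, m, pn, prolesaNet:::ag_leaf(tape, x))
    prolesaNet:::ag_seg_loss(tape, g$z, y)$value
  }
  tape <- prolesaNet:::ag_tape()
  pn <- prolesaNet:::bindParams(tape, m)
  g <- prolesaNet:::modelGraph(tape, m, pn, prolesaNet:::ag_leaf(tape, x))
  loss <- prolesaNet:::ag_seg_loss(tape, g$z, y)
  prolesaNet:::ag_backward(tape, loss)
  for (nm in c("enc1.conv1.W", "skip1.fc1W", "gate1.outW", "up1.W",
               "dec1.in1.g", "head.b")) {
    v <- get(nm, envir = m@params)
    idx <- sample(length(v), min(5, length(v)))
    fd <- fdGrad(function(vv) lossAt(nm, vv), v, idx, eps = 1e-5)
    expect_equal(as.numeric(pn[[nm]]$grad[idx]), fd, tolerance = 1e-3,
                 label = nm)
  }
})
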