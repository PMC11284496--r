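# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Feature tensors are stored channel-fastest as (C, X, Y, Z) arrays so that
# the GEMM-based C++ kernels can view one spatial position as a contiguous
# channel vector. Nodes are environments holding a value, an accumulated
# gradient, parent references and a backward closure; ag_backward() walks the
# tape in reverse creation order. Only what the segmentation networks need is
# implemented -- this is not a general autodiff library.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_leaf <- function(tape, value) ag_node(tape, value)

ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
  }
  invisible(NULL)
}

## ---- elementwise ----

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

ag_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ag_node(tape, av * bv, list(a, b),
          function(g) list(g * bv, g * av))
}

ag_relu <- function(tape, x) {
  v <- x$value
  pos <- v > 0
  ag_node(tape, v * pos, list(x), function(g) list(g * pos))
}

ag_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-x$value))
  ag_node(tape, v, list(x), function(g) list(g * v * (1 - v)))
}

## ---- convolution / pooling ----

ag_conv3d <- function(tape, x, w, b, kdim, stride = c(1L, 1L, 1L),
                      pad = (kdim - 1L) %/% 2L) {
  xv <- x$value
  out <- cpp_conv3d_fwd(xv, w$value, b$value, as.integer(kdim),
                        as.integer(stride), as.integer(pad))
  ag_node(tape, out, list(x, w, b), function(g) {
    gr <- cpp_conv3d_bwd(xv, w$value, g, as.integer(kdim),
                         as.integer(stride), as.integer(pad))
    list(gr$gx, gr$gw, as.numeric(gr$gb))
  })
}

ag_convt3d <- function(tape, x, w, b, factor) {
  xv <- x$value
  out <- cpp_convt3d_fwd(xv, w$value, b$value, as.integer(factor))
  ag_node(tape, out, list(x, w, b), function(g) {
    gr <- cpp_convt3d_bwd(xv, w$value, g, as.integer(factor))
    list(gr$gx, gr$gw, as.numeric(gr$gb))
  })
}

ag_maxpool <- function(tape, x, factor) {
  fw <- cpp_maxpool3d_fwd(x$value, as.integer(factor))
  xdim <- dim(x$value)
  ag_node(tape, fw$out, list(x), function(g) {
    list(cpp_maxpool3d_bwd(g, fw$argmax, as.integer(xdim)))
  })
}

## ---- channel-shaped ops ----

# global average pooling over all spatial positions -> length-C vector
ag_gap <- function(tape, x) {
  d <- dim(x$value)
  nsp <- prod(d[-1])
  v <- rowMeans(matrix(x$value, d[1]))
  ag_node(tape, v, list(x), function(g) {
    list(array(g / nsp, d)) # recycles channel-fastest
  })
}

# multiply each channel c of x by scalar s[c]
ag_scale_channels <- function(tape, x, s) {
  d <- dim(x$value)
  xv <- x$value
  sv <- s$value
  ag_node(tape, xv * array(sv, d), list(x, s), function(g) {
    list(g * array(sv, d), rowSums(matrix(g * xv, d[1])))
  })
}

# multiply all channels of x by a single-channel spatial map a (dim (1,X,Y,Z))
ag_mul_single <- function(tape, x, a) {
  d <- dim(x$value)
  xv <- x$value
  ab <- array(rep(as.vector(a$value), each = d[1]), d)
  ag_node(tape, xv * ab, list(x, a), function(g) {
    ga <- colSums(matrix(g * xv, d[1]))
    dim(ga) <- c(1L, d[-1])
    list(g * ab, ga)
  })
}

ag_dense <- function(tape, x, w, b) {
  xv <- x$value
  v <- as.numeric(w$value %*% xv + b$value)
  ag_node(tape, v, list(x, w, b), function(g) {
    list(as.numeric(crossprod(w$value, g)), outer(g, xv), g)
  })
}

# softmax over all spatial positions, independently per channel
ag_softmax_spatial <- function(tape, x) {
  d <- dim(x$value)
  m <- matrix(x$value, d[1])
  m <- exp(m - apply(m, 1, max))
  m <- m / rowSums(m)
  v <- array(m, d)
  ag_node(tape, v, list(x), function(g) {
    gm <- matrix(g, d[1])
    gx <- m * (gm - rowSums(gm * m))
    dim(gx) <- d
    list(gx)
  })
}

# instance normalisation: per-channel standardisation over spatial positions,
# then learnable affine (gamma, beta)
ag_instnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  n <- prod(d[-1])
  m <- matrix(x$value, d[1])
  mu <- rowMeans(m)
  xc <- m - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- gamma$value
  v <- array(xhat * gv + beta$value, d)
  ag_node(tape, v, list(x, gamma, beta), function(g) {
    gm <- matrix(g, d[1])
    gxhat <- gm * gv
    gx <- istd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    dim(gx) <- d
    list(gx, rowSums(gm * xhat), rowSums(gm))
  })
}

ag_concat_channels <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(0, c(da[1] + db[1], da[-1]))
  v[seq_len(da[1]), , , ] <- a$value
  v[da[1] + seq_len(db[1]), , , ] <- b$value
  ag_node(tape, v, list(a, b), function(g) {
    list(g[seq_len(da[1]), , , , drop = FALSE],
         g[da[1] + seq_len(db[1]), , , , drop = FALSE])
  })
}

## ---- losses ----

# Combined soft-Dice + voxelwise binary cross-entropy on logits z.
# dice = (2 sum(p y) + eps) / (sum p + sum y + eps); loss_dice = 1 - dice.
# bce is computed from logits for numerical stability.
ag_seg_loss <- function(tape, z, y, w_dice = 1, w_bce = 1, eps = 1e-6) {
  zv <- z$value
  p <- 1 / (1 + exp(-zv))
  n <- length(p)
  spy <- sum(p * y)
  sp <- sum(p)
  sy <- sum(y)
  denom <- sp + sy + eps
  dice <- (2 * spy + eps) / denom
  # log(1 + exp(z)) computed stably
  softplus <- ifelse(zv > 0, zv + log1p(exp(-zv)), log1p(exp(zv)))
  bce <- mean(softplus - y * zv)
  val <- w_dice * (1 - dice) + w_bce * bce
  ag_node(tape, val, list(z), function(g) {
    ddice_dp <- (2 * y * denom - (2 * spy + eps)) / denom^2
    gz <- w_dice * (-ddice_dp) * p * (1 - p) + w_bce * (p - y) / n
    dim(gz) <- dim(zv)
    list(g * gz)
  })
}
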