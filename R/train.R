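# Seeded CPU training loop: Adam on soft-Dice + binary cross-entropy.
# Desk-scale by design -- the intended use is fitting phantom cohorts and
# overfit smoke runs, not full-cohort training.

#' Soft Dice loss
#'
#' \code{1 - (2 sum(p y) + eps) / (sum p + sum y + eps)} with
#' \code{eps = 1e-6}; \code{p} are predicted probabilities in [0, 1] and
#' \code{y} the binary labels.
#'
#' @param prob numeric array of probabilities
#' @param label binary array of the same shape
#' @param eps smoothing constant
#' @return scalar loss in [0, 1]
#' @export
softDiceLoss <- function(prob, label, eps = 1e-6) {
  if (!identical(dim(prob), dim(label)))
    stop("probability and label shapes differ")
  1 - (2 * sum(prob * label) + eps) / (sum(prob) + sum(label) + eps)
}

lossWeights <- function(loss) {
  switch(loss,
         dice_bce = c(1, 1),
         dice = c(1, 0),
         bce = c(0, 1))
}

adamNew <- function(model) {
  st <- new.env(parent = emptyenv())
  for (nm in model@params$.order) {
    v <- get(nm, envir = model@params)
    assign(paste0("m.", nm), v * 0, envir = st)
    assign(paste0("v.", nm), v * 0, envir = st)
  }
  st$t <- 0
  st
}

adamStep <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in model@params$.order) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- beta1 * get(paste0("m.", nm), envir = st) + (1 - beta1) * g
    v <- beta2 * get(paste0("v.", nm), envir = st) + (1 - beta2) * g * g
    assign(paste0("m.", nm), m, envir = st)
    assign(paste0("v.", nm), v, envir = st)
    p <- get(nm, envir = model@params)
    assign(nm, p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
           envir = model@params)
  }
  invisible(NULL)
}

#' Train a model on a cohort of preprocessed cases
#'
#' Gradient-based fitting with seeded initialisation-independent shuffling:
#' each epoch visits every case once (shuffled), accumulating gradients
#' over \code{batchSize} cases per Adam update. The per-epoch history
#' records the mean loss and the mean training Dice (computed from the
#' same forward passes, thresholded at 0.5). In deterministic mode an
#' identical seed yields an identical history. Training aborts with a
#' diagnostic naming the epoch if the loss becomes non-finite, and stops
#' early when \code{targetDice} is reached or when the Dice has not
#' improved for \code{patience} epochs.
#'
#' @param model a \linkS4class{SegModel} (updated in place and returned)
#' @param cohort list of \linkS4class{ModelInput}
#' @param cfg a \linkS4class{TrainConfig}
#' @return a \linkS4class{TrainResult}
#' @export
trainModel <- function(model, cohort, cfg = TrainConfig()) {
  validObject(cfg)
  if (length(cohort) == 0) stop("cohort must be nonempty")
  for (ci in cohort) checkInputShape(model, dim(ci@tensor))
  w <- lossWeights(cfg@loss)
  st <- adamNew(model)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     train_dice = numeric())
  if (cfg@maxEpochs == 0L)
    return(new("TrainResult", model = model, history = hist, config = cfg))
  bestDice <- -Inf
  bad <- 0L
  withSeed(cfg@seed, {
    xs <- lapply(cohort, function(ci) aperm(ci@tensor, c(4, 3, 2, 1)))
    ys <- lapply(cohort, function(ci) {
      y <- aperm(ci@label, c(3, 2, 1))
      dim(y) <- c(1L, dim(y))
      y
    })
    for (ep in seq_len(cfg@maxEpochs)) {
      ord <- sample(length(cohort))
      epLoss <- 0
      epDice <- 0
      nb <- 0L
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[seq.int(i, min(i + cfg@batchSize - 1L, length(ord)))]
        i <- i + cfg@batchSize
        grads <- list()
        bl <- 0
        for (k in idx) {
          tape <- ag_tape()
          pn <- bindParams(tape, model)
          g <- modelGraph(tape, model, pn, ag_leaf(tape, xs[[k]]))
          loss <- ag_seg_loss(tape, g$z, ys[[k]], w_dice = w[1], w_bce = w[2])
          if (!is.finite(loss$value))
            stop(sprintf("non-finite loss at epoch %d (case %d)", ep, k))
          ag_backward(tape, loss)
          bl <- bl + loss$value
          pr <- g$p$value >= 0.5
          epDice <- epDice + {
            s <- sum(pr * ys[[k]])
            tot <- sum(pr) + sum(ys[[k]])
            if (tot == 0) 1 else 2 * s / tot
          }
          for (nm in names(pn)) {
            gg <- pn[[nm]]$grad
            if (is.null(gg)) next
            grads[[nm]] <- if (is.null(grads[[nm]])) gg else grads[[nm]] + gg
          }
        }
        nbatch <- length(idx)
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / nbatch
        adamStep(model, grads, st, cfg@learningRate)
        epLoss <- epLoss + bl
        nb <- nb + nbatch
      }
      epLoss <- epLoss / nb
      epDice <- epDice / nb
      hist <- rbind(hist, data.frame(epoch = ep, loss = epLoss,
                                     train_dice = epDice))
      if (!is.na(cfg@targetDice) && epDice >= cfg@targetDice) break
      if (!is.na(cfg@patience)) {
        if (epDice > bestDice + 1e-6) {
          bestDice <- epDice
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= cfg@patience) break
        }
      }
    }
  })
  new("TrainResult", model = model, history = hist, config = cfg)
}
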