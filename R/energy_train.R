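# Training of the energy model: total loss = DSM + lambda * trajectory
# reconstruction, minimized with Adam over all parameters (network, class
# embedding, gate logits, prototypes, interaction matrix). The trajectory
# gradient flows back through every RK4 stage by a discrete adjoint pass;
# each stage needs vector-Jacobian products of the field, i.e. a
# Hessian-vector product of the energy (gradDirectional) plus the linear
# interaction part. The rescaling factor of the interaction matrix is
# treated as a constant during differentiation.

trainableNames <- c("W1", "b1", "W2", "b2", "w3", "b3", "embed", "gamma",
                    "proto", "A")

zeroLike <- function(p) lapply(p, function(x) x * 0)

# Batched VJPs of the field f(x) = -grad_x E(x, y) + Ahat x: columns of X
# and A carry one trajectory per class; parameter cotangents sum over
# columns (they sum in the total gradient anyway), x-cotangents stay
# per-column.
fieldVJP <- function(p, Ahat, scaleA, X, yIdx, Acot, acc) {
  gd <- gradDirectional(p, X, yIdx, Acot)
  for (nm in c("W1", "b1", "W2", "b2", "w3", "embed", "gamma"))
    acc[[nm]] <- acc[[nm]] - gd[[nm]]
  acc$A <- acc$A + tcrossprod(Acot, X) / scaleA
  vx <- -gd$gx + crossprod(Ahat, Acot)
  list(vx = vx, acc = acc)
}

# Forward RK4 for all class prototypes at once (columns = classes),
# caching stage states for the adjoint pass.
trajForward <- function(p, clsIdx, steps, dt, Ahat) {
  field <- function(X)
    -netGradX(p, netForward(p, X, clsIdx)) + Ahat %*% X
  X <- p$proto[, clsIdx, drop = FALSE]
  cache <- vector("list", steps)
  for (s in seq_len(steps)) {
    k1 <- field(X)
    x2 <- X + dt / 2 * k1; k2 <- field(x2)
    x3 <- X + dt / 2 * k2; k3 <- field(x3)
    x4 <- X + dt * k3;     k4 <- field(x4)
    xn <- X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(xn)))
      stop("integration error: non-finite state at step ", s)
    cache[[s]] <- list(x = X, x2 = x2, x3 = x3, x4 = x4)
    X <- xn
  }
  list(endpoint = X, cache = cache)
}

# Discrete adjoint through the cached RK4 stages given per-class endpoint
# cotangents; returns parameter cotangents (including the prototypes).
trajBackward <- function(p, fwd, clsIdx, dt, Ahat, scaleA, endCotangent) {
  acc <- zeroLike(p)
  aX <- endCotangent
  for (s in rev(seq_along(fwd$cache))) {
    st <- fwd$cache[[s]]
    ak1 <- dt / 6 * aX; ak2 <- dt / 3 * aX; ak3 <- dt / 3 * aX
    ak4 <- dt / 6 * aX
    v <- fieldVJP(p, Ahat, scaleA, st$x4, clsIdx, ak4, acc)
    acc <- v$acc; aX <- aX + v$vx; ak3 <- ak3 + dt * v$vx
    v <- fieldVJP(p, Ahat, scaleA, st$x3, clsIdx, ak3, acc)
    acc <- v$acc; aX <- aX + v$vx; ak2 <- ak2 + dt / 2 * v$vx
    v <- fieldVJP(p, Ahat, scaleA, st$x2, clsIdx, ak2, acc)
    acc <- v$acc; aX <- aX + v$vx; ak1 <- ak1 + dt / 2 * v$vx
    v <- fieldVJP(p, Ahat, scaleA, st$x, clsIdx, ak1, acc)
    acc <- v$acc; aX <- aX + v$vx
  }
  acc$proto[, clsIdx] <- acc$proto[, clsIdx] + aX
  acc
}

# Trajectory loss and gradients for a batch: one trajectory per class
# present (all class members share the prototype start), endpoints matched
# per-sample to the batch members of that class.
trajectoryBatch <- function(p, Xc, yIdx, steps, dt, wantGrad = TRUE) {
  n <- nrow(Xc); B <- ncol(Xc)
  ri <- rescaledInteraction(p$A)
  clsIdx <- sort(unique(yIdx))
  fwd <- trajForward(p, clsIdx, steps, dt, ri$Ahat)
  loss <- 0
  cot <- matrix(0, n, length(clsIdx))
  for (ci in seq_along(clsIdx)) {
    members <- which(yIdx == clsIdx[ci])
    resid <- fwd$endpoint[, ci] - Xc[, members, drop = FALSE]
    loss <- loss + sum(colMeans(resid^2))
    cot[, ci] <- 2 * rowSums(resid) / (n * B)
  }
  grads <- NULL
  if (wantGrad) {
    tg <- trajBackward(p, fwd, clsIdx, dt, ri$Ahat, ri$scale, cot)
    grads <- tg
  }
  list(loss = loss / B, grads = grads)
}

# Global-norm gradient clipping.
clipGrads <- function(grads, maxNorm = 10) {
  tot <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(tot) && tot > maxNorm)
    grads <- lapply(grads, function(g) g * (maxNorm / tot))
  grads
}

#' Train the energy model
#'
#' Minimizes \code{DSM + lambdaTraj * trajectory reconstruction} with Adam
#' over all parameters. A stratified validation split drives early stopping
#' (patience on the validation total loss); the best-validation parameters
#' are restored. Every random draw (initialization, batch order, DSM noise)
#' flows from \code{cfg$seed}.
#'
#' @param X samples-by-genes matrix of preprocessed features in [0, 1].
#' @param y integer labels 0/1 per row.
#' @param cfg a [trainConfig()].
#' @param sampleIds optional sample identifiers recorded for the leakage
#'   audit.
#' @param geneList optional gene identifiers.
#' @return A trained \linkS4class{EnergyModel} with per-epoch loss history
#'   (columns epoch, dsm, traj, total, val) and a Youden threshold selected
#'   on the validation split.
#' @export
trainEnergyModel <- function(X, y, cfg = trainConfig(),
                             sampleIds = rownames(X),
                             geneList = colnames(X)) {
  stopifnot(is.matrix(X))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training needs both classes present")
  n <- ncol(X)
  # stratified validation split
  idx <- withSeed(childSeed(cfg$seed, 11L), {
    val <- unlist(lapply(c(0L, 1L), function(cl) {
      cand <- which(y == cl)
      sample(cand, max(1L, round(length(cand) * cfg$valFraction)))
    }))
    list(val = sort(val), train = setdiff(seq_along(y), val))
  })
  Xtr <- X[idx$train, , drop = FALSE]; ytr <- y[idx$train]
  Xva <- X[idx$val, , drop = FALSE];  yva <- y[idx$val]
  protoInit <- unname(cbind(colMeans(Xtr[ytr == 0L, , drop = FALSE]),
                            colMeans(Xtr[ytr == 1L, , drop = FALSE])))
  model <- initEnergyModel(n, cfg$widths, cfg$dEmbed,
                           seed = childSeed(cfg$seed, 12L),
                           protoInit = protoInit, geneList = geneList)
  p <- model@params
  mAdam <- zeroLike(p); vAdam <- zeroLike(p); tAdam <- 0
  beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
  XcTr <- unname(t(Xtr)); yIdxTr <- ytr + 1L
  XcVa <- unname(t(Xva)); yIdxVa <- yva + 1L
  bestVal <- Inf; bestP <- p; wait <- 0L
  hist <- vector("list", cfg$epochs)
  nTr <- length(ytr)
  # fixed validation noise so the early-stopping criterion is comparable
  # across epochs (a fresh draw would swamp real improvements)
  epsVa <- withSeed(childSeed(cfg$seed, 90000L),
                    matrix(rnorm(length(XcVa)), nrow(XcVa), ncol(XcVa)))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- withSeed(childSeed(cfg$seed, 100L + epoch), sample.int(nTr))
    starts <- seq(1, nTr, by = cfg$batch)
    edsm <- etraj <- 0
    for (bi in seq_along(starts)) {
      take <- ord[starts[bi]:min(starts[bi] + cfg$batch - 1L, nTr)]
      Xb <- XcTr[, take, drop = FALSE]; yb <- yIdxTr[take]
      eps <- withSeed(childSeed(cfg$seed, 10000L + epoch * 50L + bi),
                      matrix(rnorm(length(Xb)), nrow(Xb), ncol(Xb)))
      dsm <- dsmLossGrad(p, Xb, yb, cfg$sigmaDsm, eps)
      grads <- zeroLike(p)
      for (nm in names(dsm$grads)) grads[[nm]] <- grads[[nm]] + dsm$grads[[nm]]
      trajLoss <- 0
      if (cfg$lambdaTraj > 0) {
        tb <- trajectoryBatch(p, Xb, yb, cfg$odeSteps, cfg$odeDt)
        trajLoss <- tb$loss
        for (nm in trainableNames)
          grads[[nm]] <- grads[[nm]] + cfg$lambdaTraj * tb$grads[[nm]]
      }
      total <- dsm$loss + cfg$lambdaTraj * trajLoss
      if (!is.finite(total))
        stop("training error: divergent (non-finite) loss at epoch ", epoch)
      grads <- clipGrads(grads)
      tAdam <- tAdam + 1
      for (nm in trainableNames) {
        mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * grads[[nm]]
        vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mAdam[[nm]] / (1 - beta1^tAdam)
        vhat <- vAdam[[nm]] / (1 - beta2^tAdam)
        p[[nm]] <- p[[nm]] - cfg$lr * mhat / (sqrt(vhat) + epsAdam)
      }
      w <- length(take) / nTr
      edsm <- edsm + dsm$loss * w; etraj <- etraj + trajLoss * w
    }
    vaDsm <- dsmLossGrad(p, XcVa, yIdxVa, cfg$sigmaDsm, epsVa,
                         wantGrad = FALSE)$loss
    vaTraj <- if (cfg$lambdaTraj > 0)
      trajectoryBatch(p, XcVa, yIdxVa, cfg$odeSteps, cfg$odeDt,
                      wantGrad = FALSE)$loss else 0
    vaTotal <- vaDsm + cfg$lambdaTraj * vaTraj
    hist[[epoch]] <- data.frame(epoch = epoch, dsm = edsm, traj = etraj,
                                total = edsm + cfg$lambdaTraj * etraj,
                                val = vaTotal)
    if (epoch >= min(cfg$minEpochs, cfg$epochs)) {
      if (vaTotal < bestVal - 1e-8) {
        bestVal <- vaTotal; bestP <- p; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  model@params <- bestP
  model@trained <- TRUE
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model@seenSamples <- as.character(sampleIds)
  # Youden threshold from ROC analysis on the validation split
  sc <- decisionScore(model, Xva)
  model@threshold <- if (length(unique(yva)) == 2L)
    selectThreshold(sc, yva) else stats::median(sc)
  model
}
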