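# Gated recurrent baseline classifiers. A flat (DEA-ranked) gene vector is
# chunked into timesteps, processed by one or two recurrent stages built
# from classical (cLSTM), cross-gated (xLSTMcg) or exponential-gated
# (xLSTMeg) cells, in unidirectional or bidirectional arrangement, then
# passed through dropout and a dense sigmoid unit. Training is exact
# backpropagation through time with Adam on the binary cross-entropy loss.

#' Chunk a flat feature vector into a sequence view
#'
#' The ranked gene vector is split into \code{timesteps} contiguous steps
#' of \code{d = ceiling(n / timesteps)} features, zero-padded at the tail.
#'
#' @param x numeric vector (or samples-by-genes matrix).
#' @param timesteps number of steps T (1 <= T <= n).
#' @return List with \code{steps} (list of T matrices, d x B),
#'   \code{d}, \code{n} (original length).
#' @export
vectorToSequence <- function(x, timesteps) {
  if (is.matrix(x)) Xc <- t(x) else Xc <- matrix(x, ncol = 1)
  n <- nrow(Xc)
  if (timesteps < 1L || timesteps > n)
    stop("timesteps must be in 1..", n, " (got ", timesteps, ")")
  d <- ceiling(n / timesteps)
  pad <- d * timesteps - n
  if (pad > 0) Xc <- rbind(Xc, matrix(0, pad, ncol(Xc)))
  steps <- lapply(seq_len(timesteps), function(t)
    Xc[((t - 1) * d + 1):(t * d), , drop = FALSE])
  list(steps = steps, d = d, n = n, timesteps = timesteps)
}

#' @describeIn vectorToSequence inverse mapping: reassemble the flat
#'   vector(s) from a sequence view (padding stripped).
#' @param seqView a sequence view from [vectorToSequence()].
#' @export
sequenceToVector <- function(seqView) {
  flat <- do.call(rbind, seqView$steps)[seq_len(seqView$n), , drop = FALSE]
  if (ncol(flat) == 1L) drop(flat) else t(flat)
}

# ---- cells ---------------------------------------------------------------

# Shared-layout LSTM cell; gateAct switches the input-gate activation:
# sigmoid (cLSTM) or clamped exponential (xLSTMeg).
initLstmCell <- function(d, H, seed, kind = "clstm") {
  withSeed(seed, {
    w <- function() matrix(rnorm(H * (d + H), sd = 1 / sqrt(d + H)), H, d + H)
    list(kind = kind, Wi = w(), Wf = w(), Wo = w(), Wc = w(),
         bi = rep(0, H), bf = rep(0, H), bo = rep(0, H), bc = rep(0, H))
  })
}

lstmForward <- function(p, x, h, c, expClamp = 10) {
  z <- rbind(x, h)
  ai <- p$Wi %*% z + p$bi; af <- p$Wf %*% z + p$bf
  ao <- p$Wo %*% z + p$bo; ac <- p$Wc %*% z + p$bc
  i <- if (p$kind == "xlstmeg") exp(pmin(ai, expClamp)) else sigmoid(ai)
  if (any(!is.finite(i)))
    stop("numeric error in input gate (non-finite exponential activation)")
  f <- sigmoid(af); o <- sigmoid(ao); ct <- tanh(ac)
  cNew <- f * c + i * ct
  hNew <- o * tanh(cNew)
  list(h = hNew, c = cNew,
       cache = list(z = z, ai = ai, i = i, f = f, o = o, ct = ct,
                    cPrev = c, cNew = cNew, expClamp = expClamp))
}

lstmBackward <- function(p, cache, dh, dc) {
  tc <- tanh(cache$cNew)
  do_ <- dh * tc
  dcAll <- dc + dh * cache$o * (1 - tc^2)
  df <- dcAll * cache$cPrev
  di <- dcAll * cache$ct
  dct <- dcAll * cache$i
  dcPrev <- dcAll * cache$f
  dai <- if (p$kind == "xlstmeg")
    di * ifelse(cache$ai < cache$expClamp, cache$i, 0)
  else di * cache$i * (1 - cache$i)
  daf <- df * cache$f * (1 - cache$f)
  dao <- do_ * cache$o * (1 - cache$o)
  dac <- dct * (1 - cache$ct^2)
  g <- list(Wi = tcrossprod(dai, cache$z), bi = rowSums(dai),
            Wf = tcrossprod(daf, cache$z), bf = rowSums(daf),
            Wo = tcrossprod(dao, cache$z), bo = rowSums(dao),
            Wc = tcrossprod(dac, cache$z), bc = rowSums(dac))
  dz <- crossprod(p$Wi, dai) + crossprod(p$Wf, daf) +
    crossprod(p$Wo, dao) + crossprod(p$Wc, dac)
  H <- length(p$bi); d <- nrow(cache$z) - H
  list(grads = g, dx = dz[seq_len(d), , drop = FALSE],
       dhPrev = dz[d + seq_len(H), , drop = FALSE], dcPrev = dcPrev)
}

#' Single step of the classical LSTM cell
#'
#' Sigmoid input/forget/output gates and a tanh candidate state:
#' \code{c = f*c_prev + i*c~}, \code{h = o*tanh(c)}.
#'
#' @param params cell parameters (weights \code{Wi,Wf,Wo,Wc} of shape
#'   H x (d + H), biases \code{bi,bf,bo,bc}).
#' @param x step input (d-vector or d x B matrix).
#' @param hPrev,cPrev previous hidden/cell state (H-vector or H x B).
#' @return List with new \code{h} and \code{c}.
#' @export
clstmStep <- function(params, x, hPrev, cPrev) {
  params$kind <- "clstm"
  r <- lstmForward(params, asMat(x), asMat(hPrev), asMat(cPrev))
  list(h = r$h, c = r$c)
}

#' Single step of the exponential-gated LSTM cell
#'
#' Identical to [clstmStep()] except the input gate uses a clamped
#' exponential activation \code{i = exp(min(a_i, expClamp))}, amplifying
#' salient inputs; forget and output gates stay sigmoid.
#'
#' @inheritParams clstmStep
#' @param expClamp maximum input-gate pre-activation (overflow guard).
#' @return List with new \code{h} and \code{c}.
#' @export
xlstmegStep <- function(params, x, hPrev, cPrev, expClamp = 10) {
  params$kind <- "xlstmeg"
  r <- lstmForward(params, asMat(x), asMat(hPrev), asMat(cPrev), expClamp)
  list(h = r$h, c = r$c)
}

asMat <- function(v) if (is.matrix(v)) v else matrix(v, ncol = 1)

# Cross-gated cell: the hidden state is partitioned into S substreams;
# each substream's gates read the step input, the concatenation of all
# previous substream hiddens, and a learned cross-influence term
# M_s %*% h_concat_prev.
initXlstmcgCell <- function(d, H, S, seed) {
  if (H %% S != 0) stop("hidden_units must be divisible by substreams")
  Hs <- H %/% S
  # substream gate weights read (x, hConcatPrev, cross term): d + H + Hs wide
  withSeed(seed, {
    mk <- function() matrix(rnorm(Hs * (d + H + Hs),
                                  sd = 1 / sqrt(d + H + Hs)), Hs, d + H + Hs)
    lapply(seq_len(S), function(s)
      list(Wi = mk(), Wf = mk(), Wo = mk(), Wc = mk(),
           bi = rep(0, Hs), bf = rep(0, Hs), bo = rep(0, Hs),
           bc = rep(0, Hs),
           M = matrix(rnorm(Hs * H, sd = 1 / sqrt(H)), Hs, H)))
  })
}

#' Single step of the cross-gated LSTM cell
#'
#' @param params list of S substream parameter sets; substream gates read
#'   the input, the concatenated previous substream hiddens and the
#'   cross-influence term \code{M_s \%*\% h_concat_prev}.
#' @param x step input (d-vector or d x B matrix).
#' @param hPrev,cPrev previous concatenated hidden/cell state.
#' @return List with new concatenated \code{h} and \code{c}.
#' @export
xlstmcgStep <- function(params, x, hPrev, cPrev) {
  r <- cgForward(params, asMat(x), asMat(hPrev), asMat(cPrev))
  list(h = r$h, c = r$c)
}

cgForward <- function(subs, x, hPrev, cPrev) {
  S <- length(subs); H <- nrow(hPrev); Hs <- H %/% S
  if (H %% S != 0) stop("substream count mismatch with hidden size")
  hs <- vector("list", S); cs <- vector("list", S); caches <- vector("list", S)
  for (s in seq_len(S)) {
    p <- subs[[s]]
    cross <- p$M %*% hPrev
    z <- rbind(x, hPrev, cross)
    cSub <- cPrev[((s - 1) * Hs + 1):(s * Hs), , drop = FALSE]
    ai <- p$Wi %*% z + p$bi; af <- p$Wf %*% z + p$bf
    ao <- p$Wo %*% z + p$bo; ac <- p$Wc %*% z + p$bc
    i <- sigmoid(ai); f <- sigmoid(af); o <- sigmoid(ao); ct <- tanh(ac)
    cNew <- f * cSub + i * ct
    hNew <- o * tanh(cNew)
    hs[[s]] <- hNew; cs[[s]] <- cNew
    caches[[s]] <- list(z = z, i = i, f = f, o = o, ct = ct, cPrev = cSub,
                        cNew = cNew, cross = cross)
  }
  list(h = do.call(rbind, hs), c = do.call(rbind, cs),
       cache = list(sub = caches, hPrev = hPrev))
}

cgBackward <- function(subs, cache, dh, dc) {
  S <- length(subs); H <- nrow(dh); Hs <- H %/% S
  dX <- NULL; dHPrev <- 0 * cache$hPrev; dCPrev <- 0 * cache$hPrev
  grads <- vector("list", S)
  for (s in seq_len(S)) {
    p <- subs[[s]]; ch <- cache$sub[[s]]
    rows <- ((s - 1) * Hs + 1):(s * Hs)
    dhs <- dh[rows, , drop = FALSE]; dcs <- dc[rows, , drop = FALSE]
    tc <- tanh(ch$cNew)
    do_ <- dhs * tc
    dcAll <- dcs + dhs * ch$o * (1 - tc^2)
    df <- dcAll * ch$cPrev; di <- dcAll * ch$ct; dct <- dcAll * ch$i
    dCPrev[rows, ] <- dcAll * ch$f
    dai <- di * ch$i * (1 - ch$i); daf <- df * ch$f * (1 - ch$f)
    dao <- do_ * ch$o * (1 - ch$o); dac <- dct * (1 - ch$ct^2)
    g <- list(Wi = tcrossprod(dai, ch$z), bi = rowSums(dai),
              Wf = tcrossprod(daf, ch$z), bf = rowSums(daf),
              Wo = tcrossprod(dao, ch$z), bo = rowSums(dao),
              Wc = tcrossprod(dac, ch$z), bc = rowSums(dac))
    dz <- crossprod(p$Wi, dai) + crossprod(p$Wf, daf) +
      crossprod(p$Wo, dao) + crossprod(p$Wc, dac)
    d <- nrow(ch$z) - H - Hs
    dxs <- dz[seq_len(d), , drop = FALSE]
    dhp <- dz[d + seq_len(H), , drop = FALSE]
    dcross <- dz[d + H + seq_len(Hs), , drop = FALSE]
    g$M <- tcrossprod(dcross, cache$hPrev)
    dhp <- dhp + crossprod(p$M, dcross)
    dX <- if (is.null(dX)) dxs else dX + dxs
    dHPrev <- dHPrev + dhp
    grads[[s]] <- g
  }
  list(grads = grads, dx = dX, dhPrev = dHPrev, dcPrev = dCPrev)
}

# ---- generic cell wrappers for the stage runner --------------------------

cellNew <- function(kind, d, H, seed, substreams = 4L) {
  switch(kind,
         clstm = initLstmCell(d, H, seed, "clstm"),
         xlstmeg = initLstmCell(d, H, seed, "xlstmeg"),
         xlstmcg = initXlstmcgCell(d, H, substreams, seed),
         stop("unknown cell kind '", kind, "'"))
}

cellFwd <- function(kind, p, x, h, c, expClamp) {
  if (kind == "xlstmcg") cgForward(p, x, h, c)
  else lstmForward(p, x, h, c, expClamp)
}

cellBwd <- function(kind, p, cache, dh, dc) {
  if (kind == "xlstmcg") cgBackward(p, cache, dh, dc)
  else lstmBackward(p, cache, dh, dc)
}

cellZeroGrad <- function(kind, p) {
  if (kind == "xlstmcg") lapply(p, function(sub) lapply(sub, function(x) x * 0))
  else lapply(p[names(p) != "kind"], function(x) x * 0)
}

addByName <- function(a, b) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

cellAddGrad <- function(kind, a, b) {
  if (kind == "xlstmcg") Map(addByName, a, b) else addByName(a, b)
}

# Run one recurrent stage (uni or bi) over a step list; returns per-step
# outputs and caches for BPTT.
stageForward <- function(stage, steps, B, expClamp) {
  T <- length(steps)
  runDir <- function(p, order) {
    H <- stageHidden(stage)
    h <- matrix(0, H, B); c <- matrix(0, H, B)
    caches <- vector("list", T); outs <- vector("list", T)
    for (ti in seq_along(order)) {
      r <- cellFwd(stage$kind, p, steps[[order[ti]]], h, c, expClamp)
      h <- r$h; c <- r$c
      caches[[ti]] <- r$cache; outs[[order[ti]]] <- h
    }
    list(outs = outs, caches = caches, last = h)
  }
  fwd <- runDir(stage$fwd, seq_len(T))
  if (!stage$bidirectional)
    return(list(outs = fwd$outs, fwd = fwd, bwd = NULL))
  bwd <- runDir(stage$bwd, rev(seq_len(T)))
  outs <- lapply(seq_len(T), function(t) rbind(fwd$outs[[t]], bwd$outs[[t]]))
  list(outs = outs, fwd = fwd, bwd = bwd)
}

stageHidden <- function(stage) stage$units

# BPTT through one stage; dOuts is a list of per-step output cotangents
# (concatenated fwd/bwd rows for bidirectional stages).
stageBackward <- function(stage, fwdRes, dOuts, steps, expClamp) {
  T <- length(steps); H <- stage$units
  runDir <- function(p, caches, order, dOutDir) {
    B <- ncol(dOutDir[[1]])
    dh <- matrix(0, H, B); dc <- matrix(0, H, B)
    acc <- cellZeroGrad(stage$kind, p)
    dX <- vector("list", T)
    for (ti in rev(seq_along(order))) {
      t <- order[ti]
      r <- cellBwd(stage$kind, p, caches[[ti]], dh + dOutDir[[t]], dc)
      acc <- cellAddGrad(stage$kind, acc, r$grads)
      dh <- r$dhPrev; dc <- r$dcPrev
      dX[[t]] <- r$dx
    }
    list(grads = acc, dX = dX)
  }
  if (!stage$bidirectional) {
    r <- runDir(stage$fwd, fwdRes$fwd$caches, seq_len(T), dOuts)
    return(list(fwd = r$grads, bwd = NULL, dX = r$dX))
  }
  dF <- lapply(dOuts, function(m) m[seq_len(H), , drop = FALSE])
  dB <- lapply(dOuts, function(m) m[H + seq_len(H), , drop = FALSE])
  rf <- runDir(stage$fwd, fwdRes$fwd$caches, seq_len(T), dF)
  rb <- runDir(stage$bwd, fwdRes$bwd$caches, rev(seq_len(T)), dB)
  list(fwd = rf$grads, bwd = rb$grads,
       dX = Map(`+`, rf$dX, rb$dX))
}

# ---- classifier ----------------------------------------------------------

validDirectionSpecs <- c("Uni", "Bi", "Uni-Bi", "Bi-Uni", "Uni-Uni", "Bi-Bi")

#' Build an untrained recurrent classifier
#'
#' @param cellKind one of \code{"clstm"}, \code{"xlstmcg"},
#'   \code{"xlstmeg"}.
#' @param directionSpec one of Uni, Bi, Uni-Bi, Bi-Uni, Uni-Uni, Bi-Bi;
#'   hyphenated specs stack two recurrent stages.
#' @param units hidden units per stage (first stage, second stage).
#' @param dropout dropout rate applied after recurrent blocks during
#'   training.
#' @param timesteps sequence chunking of the gene vector.
#' @param nFeatures flat input dimension (gene count).
#' @param substreams substream count S (xlstmcg only; units must be
#'   divisible by S).
#' @param expClamp input-gate pre-activation clamp (xlstmeg only).
#' @param seed RNG seed for initialization.
#' @return A \linkS4class{RecurrentClassifier} (untrained).
#' @export
buildRecurrentClassifier <- function(cellKind, directionSpec = "Uni",
                                     units = c(128L, 64L), dropout = 0.2,
                                     timesteps = 10L, nFeatures,
                                     substreams = 4L, expClamp = 10,
                                     seed = 1L) {
  if (!directionSpec %in% validDirectionSpecs)
    stop("unknown direction spec '", directionSpec, "'; valid: ",
         paste(validDirectionSpecs, collapse = ", "))
  if (!cellKind %in% c("clstm", "xlstmcg", "xlstmeg"))
    stop("unknown cell kind '", cellKind,
         "'; valid: clstm, xlstmcg, xlstmeg")
  timesteps <- min(as.integer(timesteps), nFeatures)
  d <- ceiling(nFeatures / timesteps)
  dirs <- strsplit(directionSpec, "-", fixed = TRUE)[[1]]
  stages <- vector("list", length(dirs))
  inDim <- d
  for (i in seq_along(dirs)) {
    bi <- dirs[i] == "Bi"
    H <- as.integer(units[min(i, length(units))])
    stages[[i]] <- list(
      kind = cellKind, bidirectional = bi, units = H,
      fwd = cellNew(cellKind, inDim, H, childSeed(seed, 10L + 2L * i),
                    substreams),
      bwd = if (bi) cellNew(cellKind, inDim, H,
                            childSeed(seed, 11L + 2L * i), substreams)
            else NULL)
    inDim <- if (bi) 2L * H else H
  }
  dense <- withSeed(childSeed(seed, 30L), list(
    w = rnorm(inDim, sd = 1 / sqrt(inDim)), b = 0))
  methods::new("RecurrentClassifier",
               spec = list(cellKind = cellKind,
                           directionSpec = directionSpec,
                           units = as.integer(units), dropout = dropout,
                           timesteps = timesteps, nFeatures = nFeatures,
                           substreams = as.integer(substreams),
                           expClamp = expClamp, outputDim = inDim),
               params = list(stages = stages, dense = dense),
               trained = FALSE, threshold = 0.5,
               seenSamples = character())
}

# Forward pass through all stages; returns probabilities and caches.
recurrentForward <- function(params, sp, X, dropoutMasks = NULL) {
  seqView <- vectorToSequence(X, sp$timesteps)
  steps <- seqView$steps
  B <- ncol(steps[[1]])
  stageRes <- vector("list", length(params$stages))
  for (i in seq_along(params$stages)) {
    st <- params$stages[[i]]
    stageRes[[i]] <- stageForward(st, steps, B, sp$expClamp)
    steps <- stageRes[[i]]$outs
    if (!is.null(dropoutMasks))
      steps <- Map(function(s, m) s * m, steps,
                   dropoutMasks[[i]])
  }
  finalStage <- params$stages[[length(params$stages)]]
  final <- if (finalStage$bidirectional)
    rbind(stageRes[[length(stageRes)]]$fwd$last,
          stageRes[[length(stageRes)]]$bwd$last)
  else stageRes[[length(stageRes)]]$fwd$last
  if (!is.null(dropoutMasks))
    final <- final * dropoutMasks$final
  logits <- drop(crossprod(final, params$dense$w)) + params$dense$b
  list(prob = sigmoid(logits), final = final, stageRes = stageRes,
       seqView = seqView)
}

#' Classification scores of a recurrent classifier
#'
#' @param clf a \linkS4class{RecurrentClassifier}.
#' @param X samples-by-genes matrix (or single feature vector).
#' @return Probability of class 1 per sample.
#' @export
recurrentScore <- function(clf, X) {
  recurrentForward(clf@params, clf@spec, X)$prob
}

#' Binary cross-entropy loss
#'
#' \code{-(1/N) sum(y log p + (1-y) log(1-p))} with probabilities clipped
#' to \code{[eps, 1-eps]}.
#'
#' @param y 0/1 labels.
#' @param yhat predicted probabilities.
#' @param eps clipping epsilon.
#' @return Non-negative scalar.
#' @export
bceLoss <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a recurrent classifier with BCE and Adam
#'
#' @param X samples-by-genes matrix of [0, 1] features.
#' @param y integer 0/1 labels.
#' @param cellKind,directionSpec,units,dropout,timesteps,substreams,expClamp
#'   see [buildRecurrentClassifier()].
#' @param epochs,lr,batch optimizer settings.
#' @param seed RNG seed for initialization, batching and dropout.
#' @return A trained \linkS4class{RecurrentClassifier}.
#' @export
fitRecurrentClassifier <- function(X, y, cellKind, directionSpec = "Uni",
                                   units = c(128L, 64L), dropout = 0.2,
                                   timesteps = 10L, substreams = 4L,
                                   expClamp = 10, epochs = 80L, lr = 0.01,
                                   batch = 32L, seed = 1L) {
  stopifnot(is.matrix(X))
  y <- as.integer(y)
  clf <- buildRecurrentClassifier(cellKind, directionSpec, units, dropout,
                                  timesteps, nFeatures = ncol(X),
                                  substreams = substreams,
                                  expClamp = expClamp,
                                  seed = childSeed(seed, 1L))
  sp <- clf@spec
  params <- clf@params
  adamM <- rapply(params, function(x) x * 0, how = "replace",
                  classes = c("numeric", "matrix"))
  adamV <- adamM; tAdam <- 0
  n <- nrow(X)
  for (epoch in seq_len(epochs)) {
    ord <- withSeed(childSeed(seed, 100L + epoch), sample.int(n))
    starts <- seq(1, n, by = batch)
    for (bi in seq_along(starts)) {
      take <- ord[starts[bi]:min(starts[bi] + batch - 1L, n)]
      Xb <- X[take, , drop = FALSE]; yb <- y[take]
      masks <- makeDropoutMasks(params, sp, length(take),
                                childSeed(seed, 5000L + epoch * 60L + bi))
      bp <- recurrentBackprop(params, sp, Xb, yb, masks)
      if (!is.finite(bp$loss))
        stop("training error: divergent (non-finite) loss at epoch ", epoch)
      tAdam <- tAdam + 1
      upd <- adamUpdateTree(params, bp$grads, adamM, adamV, tAdam, lr)
      params <- upd$p; adamM <- upd$m; adamV <- upd$v
    }
  }
  clf@params <- params
  clf@trained <- TRUE
  clf@seenSamples <- as.character(rownames(X))
  clf
}

makeDropoutMasks <- function(params, sp, B, seed) {
  rate <- sp$dropout
  nStages <- length(params$stages)
  withSeed(seed, {
    masks <- vector("list", nStages)
    for (i in seq_len(nStages)) {
      st <- params$stages[[i]]
      outDim <- if (st$bidirectional) 2L * st$units else st$units
      masks[[i]] <- lapply(seq_len(sp$timesteps), function(t)
        if (rate > 0)
          matrix(stats::rbinom(outDim * B, 1, 1 - rate) / (1 - rate),
                 outDim, B)
        else matrix(1, outDim, B))
    }
    finalDim <- sp$outputDim
    masks$final <- if (rate > 0)
      matrix(stats::rbinom(finalDim * B, 1, 1 - rate) / (1 - rate),
             finalDim, B)
    else matrix(1, finalDim, B)
    masks
  })
}

# Full BPTT for one minibatch; returns loss and a gradient tree matching
# the parameter layout.
recurrentBackprop <- function(params, sp, Xb, yb, masks) {
  fw <- recurrentForward(params, sp, Xb, dropoutMasks = masks)
  B <- length(yb)
  eps <- 1e-7
  p <- pmin(pmax(fw$prob, eps), 1 - eps)
  loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
  dlogit <- (p - yb) / B                      # BCE + sigmoid shortcut
  dDenseW <- drop(fw$final %*% dlogit)
  dDenseB <- sum(dlogit)
  dFinal <- params$dense$w %o% dlogit * masks$final
  nStages <- length(params$stages)
  T <- sp$timesteps
  stageGrads <- vector("list", nStages)
  # cotangents of each stage's per-step outputs; the final hidden state
  # feeds the dense layer (for bi stages both directional lasts do)
  dOuts <- lapply(seq_len(T), function(t)
    matrix(0, nrow(dFinal), B))
  finalStage <- params$stages[[nStages]]
  if (finalStage$bidirectional) {
    H <- finalStage$units
    dOuts[[T]][seq_len(H), ] <- dFinal[seq_len(H), ]     # fwd last at t = T
    dOuts[[1]][H + seq_len(H), ] <- dFinal[H + seq_len(H), ]  # bwd last at t = 1
  } else {
    dOuts[[T]] <- dFinal
  }
  for (i in rev(seq_len(nStages))) {
    st <- params$stages[[i]]
    # undo this stage's output dropout; the last stage feeds the dense
    # layer through masks$final instead, so its sequence mask is not
    # involved in any used path
    if (i < nStages)
      dOuts <- Map(function(dm, m) dm * m, dOuts, masks[[i]])
    stepsIn <- if (i == 1L) fw$seqView$steps
               else Map(function(s, m) s * m,
                        fw$stageRes[[i - 1L]]$outs, masks[[i - 1L]])
    bk <- stageBackward(st, fw$stageRes[[i]], dOuts, stepsIn, sp$expClamp)
    stageGrads[[i]] <- list(fwd = bk$fwd, bwd = bk$bwd)
    dOuts <- bk$dX
  }
  list(loss = loss,
       grads = list(stages = stageGrads,
                    dense = list(w = dDenseW, b = dDenseB)))
}

# Adam over a nested parameter tree; gradient tree mirrors the params tree
# for numeric leaves (cell descriptor fields are skipped).
adamUpdateTree <- function(p, g, m, v, t, lr,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (!is.numeric(p)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk(p, g, m, v)
}

setMethod("show", "RecurrentClassifier", function(object) {
  sp <- object@spec
  cat("RecurrentClassifier: ", sp$cellKind, " [", sp$directionSpec,
      "], units (", paste(sp$units, collapse = ", "), "), T = ",
      sp$timesteps, if (object@trained) ", trained" else ", untrained",
      "\n", sep = "")
})
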