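# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results from first principles
# (loops, enumeration, closed forms) so they stay independent of the
# package implementation they check.

# Step-up false-discovery-rate adjustment straight from the definition.
bhStepUpOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# AUC by exhaustive pair counting (ties count 1/2).
aucPairOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Two-sided pooled-variance two-sample t-test from the textbook formulas.
pooledTOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(abs(t), nx + ny - 2, lower.tail = FALSE))
}

# Classical LSTM step, gate by gate, scalar loops only.
clstmStepOracle <- function(params, x, hPrev, cPrev) {
  H <- length(params$bi)
  z <- c(x, hPrev)
  h <- numeric(H); cNew <- numeric(H)
  for (j in seq_len(H)) {
    i <- 1 / (1 + exp(-(sum(params$Wi[j, ] * z) + params$bi[j])))
    f <- 1 / (1 + exp(-(sum(params$Wf[j, ] * z) + params$bf[j])))
    o <- 1 / (1 + exp(-(sum(params$Wo[j, ] * z) + params$bo[j])))
    ct <- tanh(sum(params$Wc[j, ] * z) + params$bc[j])
    cNew[j] <- f * cPrev[j] + i * ct
    h[j] <- o * tanh(cNew[j])
  }
  list(h = h, c = cNew)
}

# Exponential-input-gate step (no clamp), scalar loops.
xlstmegStepOracle <- function(params, x, hPrev, cPrev) {
  H <- length(params$bi)
  z <- c(x, hPrev)
  h <- numeric(H); cNew <- numeric(H)
  for (j in seq_len(H)) {
    i <- exp(sum(params$Wi[j, ] * z) + params$bi[j])
    f <- 1 / (1 + exp(-(sum(params$Wf[j, ] * z) + params$bf[j])))
    o <- 1 / (1 + exp(-(sum(params$Wo[j, ] * z) + params$bo[j])))
    ct <- tanh(sum(params$Wc[j, ] * z) + params$bc[j])
    cNew[j] <- f * cPrev[j] + i * ct
    h[j] <- o * tanh(cNew[j])
  }
  list(h = h, c = cNew)
}

# Cross-gated step with the cross terms materialized explicitly.
xlstmcgStepOracle <- function(subs, x, hPrev, cPrev) {
  S <- length(subs)
  H <- length(hPrev); Hs <- H / S
  hOut <- numeric(H); cOut <- numeric(H)
  for (s in seq_len(S)) {
    p <- subs[[s]]
    cross <- as.numeric(p$M %*% hPrev)
    z <- c(x, hPrev, cross)
    for (j in seq_len(Hs)) {
      row <- (s - 1) * Hs + j
      i <- 1 / (1 + exp(-(sum(p$Wi[j, ] * z) + p$bi[j])))
      f <- 1 / (1 + exp(-(sum(p$Wf[j, ] * z) + p$bf[j])))
      o <- 1 / (1 + exp(-(sum(p$Wo[j, ] * z) + p$bo[j])))
      ct <- tanh(sum(p$Wc[j, ] * z) + p$bc[j])
      cOut[row] <- f * cPrev[row] + i * ct
      hOut[row] <- o * tanh(cOut[row])
    }
  }
  list(h = hOut, c = cOut)
}

# Two well-separated Gaussian clusters in [0, 1]^2.
makeToyClusters <- function(seed, n = 50, sd = 0.05) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n, 0.2, sd), n),
             matrix(rnorm(2 * n, 0.8, sd), n))
  X <- pmin(pmax(X, 0), 1)
  rownames(X) <- paste0("s", seq_len(2 * n))
  colnames(X) <- c("gA", "gB")
  list(X = X, y = c(rep(0L, n), rep(1L, n)))
}

# Fast nearest-centroid model for exercising protocol plumbing without the
# cost of the full classifiers.
registerCentroidModel <- function() {
  registerModel("centroid",
    fit = function(X, y, seed, config = NULL) {
      obj <- list(c0 = colMeans(X[y == 0, , drop = FALSE]),
                  c1 = colMeans(X[y == 1, , drop = FALSE]))
      attr(obj, "threshold") <- 0
      attr(obj, "seenSamples") <- rownames(X)
      obj
    },
    score = function(object, X) {
      d0 <- sqrt(rowSums(sweep(X, 2, object$c0)^2))
      d1 <- sqrt(rowSums(sweep(X, 2, object$c1)^2))
      d0 - d1
    })
}
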