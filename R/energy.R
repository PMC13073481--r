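# Class-conditioned energy model: scalar energy E(X, Y) from an ELU MLP on
# gated features concatenated with a class embedding; composite vector
# field -grad_X E + A_hat X integrated by RK4; trained by denoising score
# matching plus trajectory reconstruction.
#
# All derivatives are exact and hand-coded. The DSM objective contains
# grad_X E, so its parameter gradient needs second-order terms; these are
# obtained by a forward(tangent)-over-reverse pass through the network
# (gradDirectional below), which also yields Hessian-vector products for
# the adjoint pass through the RK4 solver.

#' Training configuration for the energy model
#'
#' @param sigmaDsm denoising-score-matching noise SD (> 0). Features live
#'   in [0, 1], so 0.1 is one tenth of the input range.
#' @param lambdaTraj weight of the trajectory reconstruction loss (>= 0);
#'   0 reduces training to pure DSM.
#' @param odeSteps RK4 step count T (>= 1).
#' @param odeDt RK4 step size h (> 0); defaults give unit integration time.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch minibatch size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param minEpochs burn-in before early stopping starts tracking the best
#'   validation loss; the trajectory term transiently rises while the
#'   energy landscape forms, so stopping is deferred past that phase.
#' @param valFraction fraction of training data held out for early stopping
#'   and threshold selection.
#' @param widths MLP hidden layer widths.
#' @param dEmbed class embedding dimension.
#' @param seed RNG seed governing every random draw of the run.
#' @return A list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(sigmaDsm = 0.1, lambdaTraj = 1.0, odeSteps = 10L,
                        odeDt = 0.1, lr = 0.01, epochs = 100L, batch = 64L,
                        patience = 25L, minEpochs = 30L, valFraction = 0.2,
                        widths = c(128L, 64L), dEmbed = 8L, seed = 1L) {
  if (!is.finite(sigmaDsm) || sigmaDsm <= 0)
    stop("invalid parameter: 'sigmaDsm' must be > 0")
  if (!is.finite(lambdaTraj) || lambdaTraj < 0)
    stop("invalid parameter: 'lambdaTraj' must be >= 0")
  if (odeSteps < 1L) stop("invalid parameter: 'odeSteps' must be >= 1")
  if (!is.finite(odeDt) || odeDt <= 0)
    stop("invalid parameter: 'odeDt' must be > 0")
  structure(list(sigmaDsm = sigmaDsm, lambdaTraj = lambdaTraj,
                 odeSteps = as.integer(odeSteps), odeDt = odeDt, lr = lr,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 patience = as.integer(patience),
                 minEpochs = as.integer(minEpochs),
                 valFraction = valFraction,
                 widths = as.integer(widths), dEmbed = as.integer(dEmbed),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Initialize an untrained energy model
#'
#' Weights are drawn with fan-in scaling, the output layer small so the
#' initial energy landscape is nearly flat; gate logits start at 0 (gates
#' at 0.5), the interaction matrix at 0, prototypes at 0.5 (centre of the
#' input domain) unless per-class data means are supplied.
#'
#' @param nGenes feature dimension.
#' @param widths hidden layer widths of the ELU MLP.
#' @param dEmbed class embedding dimension.
#' @param seed RNG seed for weight initialization.
#' @param protoInit optional nGenes x 2 matrix of per-class prototype
#'   starting values (column 1 = Control, column 2 = Diseased).
#' @param geneList optional gene identifiers.
#' @return An \linkS4class{EnergyModel}.
#' @export
initEnergyModel <- function(nGenes, widths = c(128L, 64L), dEmbed = 8L,
                            seed = 1L, protoInit = NULL,
                            geneList = character()) {
  stopifnot(nGenes >= 1, length(widths) == 2)
  m <- nGenes + dEmbed
  params <- withSeed(seed, list(
    W1 = matrix(rnorm(widths[1] * m, sd = 1 / sqrt(m)), widths[1], m),
    b1 = rep(0, widths[1]),
    W2 = matrix(rnorm(widths[2] * widths[1], sd = 1 / sqrt(widths[1])),
                widths[2], widths[1]),
    b2 = rep(0, widths[2]),
    w3 = rnorm(widths[2], sd = 0.01 / sqrt(widths[2])),
    b3 = 0,
    embed = matrix(rnorm(dEmbed * 2, sd = 0.5), dEmbed, 2),
    gamma = rep(0, nGenes),
    proto = if (is.null(protoInit)) matrix(0.5, nGenes, 2) else protoInit,
    A = matrix(0, nGenes, nGenes)
  ))
  methods::new("EnergyModel", params = params,
               hyper = list(widths = as.integer(widths),
                            dEmbed = as.integer(dEmbed),
                            nGenes = as.integer(nGenes)),
               geneList = as.character(geneList), trained = FALSE,
               threshold = NA_real_, seenSamples = character(),
               history = data.frame())
}

# ---- forward / reverse passes (features as columns) ----------------------

# Forward pass; X is nGenes x B, yIdx in {1, 2} length 1 or B.
# Returns cached activations for reverse passes.
netForward <- function(p, X, yIdx) {
  B <- ncol(X)
  if (length(yIdx) == 1L) yIdx <- rep(yIdx, B)
  g <- sigmoid(p$gamma)
  U <- rbind(g * X, p$embed[, yIdx, drop = FALSE])
  A1 <- p$W1 %*% U + p$b1
  H1 <- elu(A1)
  A2 <- p$W2 %*% H1 + p$b2
  H2 <- elu(A2)
  E <- drop(crossprod(H2, p$w3)) + p$b3
  list(U = U, A1 = A1, H1 = H1, A2 = A2, H2 = H2, E = E, g = g, yIdx = yIdx)
}

# grad_X E per column (exact reverse mode).
netGradX <- function(p, fw) {
  n <- length(p$gamma)
  dA2 <- p$w3 * eluD(fw$A2)
  dH1 <- crossprod(p$W2, dA2)
  dA1 <- dH1 * eluD(fw$A1)
  dU <- crossprod(p$W1, dA1)
  fw$g * dU[seq_len(n), , drop = FALSE]
}

# Forward-over-reverse: for D_b = r_b' grad_X E(x_b, y_b), return
# sum_b grad_theta D_b and per-column grad_x D (the Hessian-vector
# product H r). X, R are nGenes x B.
gradDirectional <- function(p, X, yIdx, R) {
  n <- length(p$gamma); d <- nrow(p$embed); B <- ncol(X)
  if (length(yIdx) == 1L) yIdx <- rep(yIdx, B)
  fw <- netForward(p, X, yIdx)
  g <- fw$g
  # tangent pass with dx = R
  dU <- rbind(g * R, matrix(0, d, B))
  dA1 <- p$W1 %*% dU
  dH1 <- eluD(fw$A1) * dA1
  dA2 <- p$W2 %*% dH1
  dH2 <- eluD(fw$A2) * dA2
  D <- drop(crossprod(dH2, p$w3))
  # reverse pass on S = sum_b D_b
  p_dH2 <- matrix(p$w3, nrow = length(p$w3), ncol = B)
  p_A2 <- p_dH2 * eluD2(fw$A2) * dA2
  p_dA2 <- p_dH2 * eluD(fw$A2)
  gW2 <- tcrossprod(p_dA2, dH1)
  p_dH1 <- crossprod(p$W2, p_dA2)
  p_A1 <- p_dH1 * eluD2(fw$A1) * dA1
  p_dA1 <- p_dH1 * eluD(fw$A1)
  gW1 <- tcrossprod(p_dA1, dU)
  p_dU <- crossprod(p$W1, p_dA1)
  # primal chain
  gW2 <- gW2 + tcrossprod(p_A2, fw$H1)
  gb2 <- rowSums(p_A2)
  p_H1 <- crossprod(p$W2, p_A2)
  p_A1 <- p_A1 + p_H1 * eluD(fw$A1)
  gW1 <- gW1 + tcrossprod(p_A1, fw$U)
  gb1 <- rowSums(p_A1)
  p_U <- crossprod(p$W1, p_A1)
  gw3 <- rowSums(dH2)
  featRows <- seq_len(n)
  p_emb <- p_U[n + seq_len(d), , drop = FALSE]
  gembed <- matrix(0, d, 2)
  for (cls in 1:2)
    if (any(fw$yIdx == cls))
      gembed[, cls] <- rowSums(p_emb[, fw$yIdx == cls, drop = FALSE])
  gg <- rowSums(p_U[featRows, , drop = FALSE] * X) +
    rowSums(p_dU[featRows, , drop = FALSE] * R)
  ggamma <- gg * g * (1 - g)
  gx <- g * p_U[featRows, , drop = FALSE]
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, w3 = gw3, b3 = 0,
       embed = gembed, gamma = ggamma, gx = gx, D = D)
}

# ---- public operations ---------------------------------------------------

#' Scalar energy of an input under a class label
#'
#' @param model an \linkS4class{EnergyModel}.
#' @param X numeric vector of length nGenes, or a samples-by-genes matrix.
#' @param Y class label 0 (Control) or 1 (Diseased); scalar or one per row.
#' @return Numeric vector of energies (one per row of \code{X}).
#' @export
energy <- function(model, X, Y) {
  Xc <- asColumns(model, X)
  if (!all(Y %in% c(0, 1))) stop("Y must be 0 or 1")
  netForward(model@params, Xc, as.integer(Y) + 1L)$E
}

asColumns <- function(model, X) {
  n <- model@hyper$nGenes
  if (is.matrix(X)) {
    if (ncol(X) != n)
      stop("dimension mismatch: expected ", n, " features, got ", ncol(X))
    t(X)
  } else {
    if (length(X) != n)
      stop("dimension mismatch: expected ", n, " features, got ", length(X))
    matrix(X, ncol = 1)
  }
}

# Spectrally rescaled interaction matrix: A / max(1, max row abs sum),
# keeping the linear part of the field non-expansive.
rescaledInteraction <- function(A) {
  c <- max(1, max(rowSums(abs(A))))
  list(Ahat = A / c, scale = c)
}

#' Composite vector field of the model
#'
#' \code{F(X, Y) = -grad_X E(X, Y) + A_hat X}: the conservative force (the
#' exact negative energy gradient) plus the residual interaction force given
#' by the rescaled gene-gene interaction matrix.
#'
#' @inheritParams energy
#' @return Matrix of field vectors, same layout as \code{X} (rows =
#'   samples when \code{X} is a matrix, else a vector).
#' @export
vectorField <- function(model, X, Y) {
  Xc <- asColumns(model, X)
  p <- model@params
  fw <- netForward(p, Xc, as.integer(Y) + 1L)
  f <- -netGradX(p, fw) + rescaledInteraction(p$A)$Ahat %*% Xc
  if (is.matrix(X)) t(f) else drop(f)
}

#' Classic fourth-order Runge-Kutta integration of an arbitrary field
#'
#' @param field function taking and returning a numeric state vector.
#' @param x0 initial state.
#' @param steps number of RK4 steps (>= 1).
#' @param dt step size.
#' @return Matrix of states, (steps + 1) rows; row 1 is \code{x0}.
#' @export
rk4Path <- function(field, x0, steps, dt) {
  stopifnot(steps >= 1, dt > 0)
  states <- matrix(NA_real_, steps + 1, length(x0))
  states[1, ] <- x0
  x <- x0
  for (s in seq_len(steps)) {
    k1 <- field(x)
    k2 <- field(x + dt / 2 * k1)
    k3 <- field(x + dt / 2 * k2)
    k4 <- field(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x)))
      stop("integration error: non-finite state at step ", s)
    states[s + 1, ] <- x
  }
  states
}

#' Generate a trajectory from a class prototype
#'
#' Integrates the model's vector field with RK4 starting from the class
#' prototype (or a supplied start state); the endpoint is the generated
#' sample.
#'
#' @param model an \linkS4class{EnergyModel}.
#' @param Y class label 0/1.
#' @param steps RK4 step count.
#' @param dt RK4 step size.
#' @param x0 optional start state overriding the class prototype.
#' @return A \linkS4class{Trajectory}.
#' @export
rk4Integrate <- function(model, Y, steps = 10L, dt = 0.1, x0 = NULL) {
  stopifnot(Y %in% c(0, 1))
  p <- model@params
  if (is.null(x0)) x0 <- p$proto[, as.integer(Y) + 1L]
  Ahat <- rescaledInteraction(p$A)$Ahat
  yIdx <- as.integer(Y) + 1L
  field <- function(x) {
    xc <- matrix(x, ncol = 1)
    drop(-netGradX(p, netForward(p, xc, yIdx)) + Ahat %*% xc)
  }
  methods::new("Trajectory", states = rk4Path(field, x0, steps, dt),
               classLabel = as.integer(Y))
}

#' @describeIn rk4Integrate endpoint (generated sample) of a trajectory.
#' @param traj a \linkS4class{Trajectory}.
#' @export
trajectoryEndpoint <- function(traj) traj@states[nrow(traj@states), ]

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", nrow(object@states) - 1L, " RK4 steps in ",
      ncol(object@states), "-dim feature space, class ",
      object@classLabel, "\n", sep = "")
})

#' Denoising score matching loss
#'
#' For corrupted inputs \code{x~ = x + sigma * eps}, the loss is the batch
#' mean of \code{|| -grad_x~ E(x~, y) - (x - x~) / sigma^2 ||^2}: the
#' negative energy gradient at the noisy point is matched to the true
#' denoising direction.
#'
#' @param model an \linkS4class{EnergyModel}.
#' @param X samples-by-genes matrix.
#' @param Y labels 0/1 per row.
#' @param sigma noise SD (> 0).
#' @param seed RNG seed for the noise draw.
#' @return Non-negative scalar loss.
#' @export
dsmLoss <- function(model, X, Y, sigma = 0.1, seed = 1L) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("invalid parameter: 'sigma' must be > 0")
  Xc <- asColumns(model, X)
  eps <- withSeed(seed, matrix(rnorm(length(Xc)), nrow(Xc), ncol(Xc)))
  dsmLossGrad(model@params, Xc, as.integer(Y) + 1L, sigma, eps,
              wantGrad = FALSE)$loss
}

# DSM loss and (optionally) exact parameter gradients given a fixed noise
# draw. Xc is nGenes x B.
dsmLossGrad <- function(p, Xc, yIdx, sigma, eps, wantGrad = TRUE) {
  Xt <- Xc + sigma * eps
  fw <- netForward(p, Xt, yIdx)
  s <- -netGradX(p, fw)             # model score at noisy points
  r <- s + eps / sigma              # s - (x - x~)/sigma^2, since x - x~ = -sigma*eps
  B <- ncol(Xc)
  loss <- sum(r * r) / B
  if (!wantGrad) return(list(loss = loss))
  gd <- gradDirectional(p, Xt, yIdx, r)
  scale <- -2 / B
  grads <- list(W1 = scale * gd$W1, b1 = scale * gd$b1,
                W2 = scale * gd$W2, b2 = scale * gd$b2,
                w3 = scale * gd$w3, b3 = 0,
                embed = scale * gd$embed, gamma = scale * gd$gamma)
  list(loss = loss, grads = grads)
}

#' Trajectory reconstruction loss
#'
#' Mean squared error between a trajectory endpoint and a real sample.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param x real feature vector of matching dimension.
#' @return Non-negative scalar.
#' @export
trajectoryLoss <- function(traj, x) {
  end <- trajectoryEndpoint(traj)
  if (length(end) != length(x))
    stop("dimension mismatch: endpoint has ", length(end),
         " features, x has ", length(x))
  mean((end - x)^2)
}

#' Energy-difference decision score
#'
#' \code{E(X, 0) - E(X, 1)}: higher values are stronger evidence for the
#' diseased class (its energy is lower).
#'
#' @param model an \linkS4class{EnergyModel}.
#' @param X feature vector or samples-by-genes matrix.
#' @return Numeric score per sample.
#' @export
decisionScore <- function(model, X) {
  energy(model, X, 0) - energy(model, X, 1)
}

#' Youden-optimal decision threshold from ROC analysis
#'
#' Scans midpoints between consecutive distinct scores (plus one cut below
#' the minimum) and returns the threshold maximizing Youden's
#' J = sensitivity + specificity - 1, with ties broken toward the lower
#' threshold. Prediction rule: class 1 iff score strictly exceeds the
#' threshold.
#'
#' @param scores numeric decision scores.
#' @param labels 0/1 labels.
#' @return The selected threshold.
#' @export
selectThreshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("threshold selection needs both classes")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2)
  j <- vapply(cand, function(th) {
    pred <- as.integer(scores > th)
    sens <- sum(pred == 1L & labels == 1L) / sum(labels == 1L)
    spec <- sum(pred == 0L & labels == 0L) / sum(labels == 0L)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]  # first index = lowest qualifying threshold
}

#' Predict class labels from the energy-difference score
#'
#' @param object a trained \linkS4class{EnergyModel}.
#' @param newdata samples-by-genes matrix (or single feature vector).
#' @param threshold decision threshold; defaults to the model's stored one.
#' @return Integer labels (1 iff score > threshold; ties go to class 0).
#' @export
setMethod("predict", "EnergyModel", function(object, newdata,
                                             threshold = object@threshold) {
  if (is.na(threshold)) stop("no decision threshold set")
  as.integer(decisionScore(object, newdata) > threshold)
})

#' Generate samples from a class prototype
#'
#' Integrates \code{n} RK4 trajectories from jittered prototype starts
#' (\code{x0 = prototype + N(0, jitterSd^2)}) and returns the endpoints.
#'
#' @param model a trained \linkS4class{EnergyModel}.
#' @param Y class label 0/1.
#' @param n number of samples.
#' @param jitterSd SD of the start-state jitter (0 = identical endpoints).
#' @param steps,dt RK4 horizon.
#' @param seed RNG seed.
#' @return n-by-nGenes matrix of generated samples.
#' @export
generateFromPrototype <- function(model, Y, n, jitterSd = 0.05,
                                  steps = 10L, dt = 0.1, seed = 1L) {
  proto <- model@params$proto[, as.integer(Y) + 1L]
  starts <- withSeed(seed,
    matrix(rnorm(n * length(proto), sd = jitterSd), n) +
      matrix(proto, n, length(proto), byrow = TRUE))
  t(apply(starts, 1, function(x0)
    trajectoryEndpoint(rk4Integrate(model, Y, steps, dt, x0 = x0))))
}

setMethod("show", "EnergyModel", function(object) {
  h <- object@hyper
  cat("EnergyModel: ", h$nGenes, " genes, MLP widths (",
      paste(h$widths, collapse = ", "), "), embedding dim ", h$dEmbed,
      if (object@trained) ", trained" else ", untrained",
      if (!is.na(object@threshold))
        sprintf(", threshold %.4f", object@threshold) else "",
      "\n", sep = "")
})
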