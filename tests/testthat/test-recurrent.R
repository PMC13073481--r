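test_that("sequence chunking pads the tail and round-trips", {
  v6 <- vectorToSequence(1:6, 3)
  expect_equal(v6$d, 2)
  expect_equal(v6$steps[[3]][, 1], c(5, 6))
  v5 <- vectorToSequence(1:5, 3)
  expect_equal(v5$d, 2)
  expect_equal(v5$steps[[3]][, 1], c(5, 0))  # trailing zero pad
  expect_equal(sequenceToVector(v5), 1:5)
  X <- matrix(runif(12), 2, 6)
  expect_equal(sequenceToVector(vectorToSequence(X, 4)), X)
  expect_error(vectorToSequence(1:3, 5), "timesteps")
})

test_that("zero-parameter cells follow their closed forms", {
  d <- 2; H <- 3
  zeroP <- list(Wi = matrix(0, H, d + H), Wf = matrix(0, H, d + H),
                Wo = matrix(0, H, d + H), Wc = matrix(0, H, d + H),
                bi = rep(0, H), bf = rep(0, H), bo = rep(0, H),
                bc = rep(0, H))
  x <- c(0.4, -0.2); h0 <- rep(0, H); c0 <- c(1, -1, 0.5)
  r <- clstmStep(zeroP, x, h0, c0)
  # i = f = o = 0.5, candidate 0: c = 0.5 c_prev, h = 0.5 tanh(0.5 c_prev)
  expect_equal(drop(r$c), 0.5 * c0)
  expect_equal(drop(r$h), 0.5 * tanh(0.5 * c0))
  rz <- clstmStep(zeroP, c(0, 0), h0, rep(0, H))
  expect_equal(drop(rz$h), rep(0, H))
  expect_equal(drop(rz$c), rep(0, H))
  # exponential gate: i = exp(0) = 1, c = 0.5 c_prev + 1 * 0
  re <- xlstmegStep(zeroP, x, h0, c0)
  expect_equal(drop(re$c), 0.5 * c0)
})

test_that("the exponential gate clamps at its pre-activation cap", {
  d <- 1; H <- 1
  p <- list(Wi = matrix(c(100, 0), 1), Wf = matrix(0, 1, 2),
            Wo = matrix(0, 1, 2), Wc = matrix(c(1, 0), 1),
            bi = 0, bf = 0, bo = 0, bc = 0)
  # pre-activation 100 * 0.5 = 50 > clamp 10: i = exp(10) exactly
  r <- xlstmegStep(p, 0.5, 0, 0, expClamp = 10)
  expect_equal(drop(r$c), exp(10) * tanh(0.5))
  # below the clamp the unclamped oracle applies
  r2 <- xlstmegStep(p, 0.05, 0, 0, expClamp = 10)
  o <- xlstmegStepOracle(p, 0.05, 0, 0)
  expect_equal(drop(r2$h), o$h, tolerance = 1e-10)
  expect_equal(drop(r2$c), o$c, tolerance = 1e-10)
})

test_that("cell steps match independent gate-by-gate oracles", {
  set.seed(41)
  d <- 3; H <- 4
  mk <- function() matrix(rnorm(H * (d + H), sd = 0.5), H, d + H)
  p <- list(Wi = mk(), Wf = mk(), Wo = mk(), Wc = mk(),
            bi = rnorm(H), bf = rnorm(H), bo = rnorm(H), bc = rnorm(H))
  x <- rnorm(d); h0 <- rnorm(H); c0 <- rnorm(H)
  r <- clstmStep(p, x, h0, c0)
  o <- clstmStepOracle(p, x, h0, c0)
  expect_equal(drop(r$h), o$h, tolerance = 1e-10)
  expect_equal(drop(r$c), o$c, tolerance = 1e-10)
  re <- xlstmegStep(p, x, h0, c0, expClamp = 50)
  oe <- xlstmegStepOracle(p, x, h0, c0)
  expect_equal(drop(re$h), oe$h, tolerance = 1e-10)
  expect_equal(drop(re$c), oe$c, tolerance = 1e-10)
  # cross-gated, S = 2 substreams
  S <- 2; Hs <- H / S
  mks <- function() matrix(rnorm(Hs * (d + H + Hs), sd = 0.5), Hs,
                           d + H + Hs)
  subs <- lapply(1:S, function(s)
    list(Wi = mks(), Wf = mks(), Wo = mks(), Wc = mks(),
         bi = rnorm(Hs), bf = rnorm(Hs), bo = rnorm(Hs), bc = rnorm(Hs),
         M = matrix(rnorm(Hs * H), Hs, H)))
  rc <- xlstmcgStep(subs, x, h0, c0)
  oc <- xlstmcgStepOracle(subs, x, h0, c0)
  expect_equal(drop(rc$h), oc$h, tolerance = 1e-10)
  expect_equal(drop(rc$c), oc$c, tolerance = 1e-10)
})

test_that("cross-gated cell with S = 1 and zero cross matrix is a cLSTM", {
  set.seed(43)
  d <- 2; H <- 3
  mk <- function() matrix(rnorm(H * (d + H), sd = 0.5), H, d + H)
  base <- list(Wi = mk(), Wf = mk(), Wo = mk(), Wc = mk(),
               bi = rnorm(H), bf = rnorm(H), bo = rnorm(H), bc = rnorm(H))
  # same weights, cross-input columns present but the cross term is zero
  ext <- function(W) cbind(W, matrix(rnorm(H * H), H, H))
  sub <- list(Wi = ext(base$Wi), Wf = ext(base$Wf), Wo = ext(base$Wo),
              Wc = ext(base$Wc), bi = base$bi, bf = base$bf, bo = base$bo,
              bc = base$bc, M = matrix(0, H, H))
  x <- rnorm(d); h0 <- rnorm(H); c0 <- rnorm(H)
  rc <- xlstmcgStep(list(sub), x, h0, c0)
  rl <- clstmStep(base, x, h0, c0)
  expect_equal(rc$h, rl$h, tolerance = 1e-12)
  expect_equal(rc$c, rl$c, tolerance = 1e-12)
})

test_that("BCE matches its closed forms and clipping bound", {
  expect_lt(bceLoss(1, 1 - 1e-9), 1e-6)
  expect_equal(bceLoss(1, 0.5), log(2))
  expect_equal(bceLoss(c(1, 0), c(0.9, 0.1)), -log(0.9), tolerance = 1e-12)
  expect_error(bceLoss(c(1, 0), 0.5), "length mismatch")
  # minimized iff predictions match labels (up to epsilon clipping)
  expect_lt(bceLoss(c(0, 1), c(1e-9, 1)), 1e-6)
  expect_gt(bceLoss(c(0, 1), c(0.9, 0.1)), 1)
})

test_that("architecture specs control output dimension and validity", {
  uni <- buildRecurrentClassifier("clstm", "Uni", units = c(8L),
                                  timesteps = 2L, nFeatures = 6L, seed = 1)
  expect_equal(uni@spec$outputDim, 8L)
  bi <- buildRecurrentClassifier("clstm", "Bi", units = c(8L),
                                 timesteps = 2L, nFeatures = 6L, seed = 1)
  expect_equal(bi@spec$outputDim, 16L)
  expect_error(buildRecurrentClassifier("clstm", "Tri", nFeatures = 6L),
               "Uni")
  expect_error(buildRecurrentClassifier("gru", "Uni", nFeatures = 6L),
               "cell kind")
})

test_that("forward pass without dropout is deterministic", {
  clf <- buildRecurrentClassifier("xlstmeg", "Bi-Uni", units = c(6L, 4L),
                                  dropout = 0, timesteps = 3L,
                                  nFeatures = 7L, seed = 5)
  X <- matrix(runif(21), 3, 7)
  expect_identical(recurrentScore(clf, X), recurrentScore(clf, X))
})

test_that("all three cell kinds separate the toy clusters", {
  d <- makeToyClusters(17, n = 40)
  for (kind in c("clstm", "xlstmcg", "xlstmeg")) {
    accs <- vapply(1:3, function(seed) {
      clf <- fitRecurrentClassifier(d$X, d$y, kind, "Uni", units = c(16L),
                                    dropout = 0.1, timesteps = 1L,
                                    epochs = 40L, seed = seed,
                                    substreams = 4L)
      mean(as.integer(recurrentScore(clf, d$X) > 0.5) == d$y)
    }, numeric(1))
    expect_gte(min(accs), 0.9)
  }
})
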