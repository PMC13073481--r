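randomModel <- function(n = 4, seed = 1) {
  m <- initEnergyModel(n, widths = c(8, 6), dEmbed = 3, seed = seed)
  p <- m@params
  set.seed(seed + 100)
  p$w3 <- rnorm(6, sd = 0.5)
  p$gamma <- rnorm(n, sd = 0.5)
  p$A <- matrix(rnorm(n * n, sd = 0.1 / n), n, n)  # inside the unit ball
  m@params <- p
  m
}

test_that("energy is a finite deterministic scalar per class", {
  m <- randomModel()
  x <- runif(4)
  e0 <- energy(m, x, 0); e1 <- energy(m, x, 1)
  expect_true(is.finite(e0) && is.finite(e1))
  expect_identical(e0, energy(m, x, 0))
  expect_error(energy(m, runif(5), 0), "dimension mismatch")
})

test_that("a zero network gives zero energy and zero conservative force", {
  m <- initEnergyModel(3, widths = c(5, 4), dEmbed = 2, seed = 1)
  p <- m@params
  for (nm in c("W1", "b1", "W2", "b2", "w3", "b3")) p[[nm]] <- p[[nm]] * 0
  p$A <- p$A * 0
  m@params <- p
  x <- runif(3)
  expect_equal(energy(m, x, 0), 0)
  expect_equal(energy(m, x, 1), 0)
  expect_equal(vectorField(m, x, 0), rep(0, 3))
})

test_that("analytic input gradient matches central finite differences", {
  for (seed in 1:4) {
    m <- randomModel(n = 5, seed = seed)
    set.seed(seed)
    for (rep in 1:5) {
      x <- runif(5); y <- sample(0:1, 1)
      f <- vectorField(m, x, y)
      Ahat <- m@params$A / max(1, max(rowSums(abs(m@params$A))))
      gradE <- drop(Ahat %*% x) - f           # recover -(-gradE) part
      h <- 1e-4
      fd <- vapply(1:5, function(i) {
        xp <- x; xm <- x; xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
        (energy(m, xp, y) - energy(m, xm, y)) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(gradE - fd)) / max(max(abs(fd)), 1e-8), 1e-4)
    }
  }
})

test_that("RK4 reproduces the linear decay solution to 1e-6", {
  # dx/dt = -x, x(0) = 1, integrated to t = 1 at h = 0.1
  path <- rk4Path(function(x) -x, x0 = 1, steps = 10, dt = 0.1)
  expect_equal(path[11, 1], exp(-1), tolerance = 1e-6)
  expect_equal(path[1, 1], 1)
})

test_that("RK4 shows fourth-order convergence on a smooth field", {
  # quadratic energy E = ||x - c||^2 / 2 gives the field c - x with
  # solution x(t) = c + (x0 - c) exp(-t)
  cvec <- c(0.3, 0.7)
  field <- function(x) cvec - x
  exact <- cvec + (c(1, 0) - cvec) * exp(-1)
  errAt <- function(h) {
    p <- rk4Path(field, c(1, 0), steps = round(1 / h), dt = h)
    max(abs(p[nrow(p), ] - exact))
  }
  e1 <- errAt(0.1); e2 <- errAt(0.05)
  order <- log2(e1 / e2)
  expect_gte(order, 3.5)
  expect_lt(e2 * 14, e1)  # roughly 16-fold drop per halving
})

test_that("a zero field leaves the trajectory at the prototype", {
  m <- initEnergyModel(3, widths = c(5, 4), dEmbed = 2, seed = 1)
  p <- m@params
  for (nm in c("W1", "b1", "W2", "b2", "w3", "b3")) p[[nm]] <- p[[nm]] * 0
  p$A <- p$A * 0
  p$proto[, 2] <- c(0.1, 0.5, 0.9)
  m@params <- p
  traj <- rk4Integrate(m, 1, steps = 5, dt = 0.1)
  expect_true(all(apply(traj@states, 1, function(r)
    all(r == c(0.1, 0.5, 0.9)))))
  expect_equal(trajectoryEndpoint(traj), c(0.1, 0.5, 0.9))
})

test_that("non-finite states abort integration naming the step", {
  expect_error(rk4Path(function(x) x * NA, 1, steps = 3, dt = 0.1),
               "step 1")
})

test_that("DSM loss is non-negative, seeded, and guards sigma", {
  m <- randomModel()
  X <- matrix(runif(12), 3, 4)
  y <- c(0, 1, 0)
  l1 <- dsmLoss(m, X, y, sigma = 0.1, seed = 5)
  l2 <- dsmLoss(m, X, y, sigma = 0.1, seed = 5)
  expect_gte(l1, 0)
  expect_identical(l1, l2)
  expect_false(identical(l1, dsmLoss(m, X, y, sigma = 0.1, seed = 6)))
  expect_error(dsmLoss(m, X, y, sigma = 0), "sigma")
})

test_that("trajectory loss is the endpoint MSE with its symmetries", {
  tr <- methods::new("Trajectory",
                     states = rbind(c(0, 0), c(0, 0)), classLabel = 1L)
  expect_equal(trajectoryLoss(tr, c(0, 0)), 0)
  expect_equal(trajectoryLoss(tr, c(1, 1)), 1)
  expect_error(trajectoryLoss(tr, c(1, 1, 1)), "dimension mismatch")
  tr2 <- methods::new("Trajectory",
                      states = rbind(c(0, 0), c(0.2, 0.9)), classLabel = 0L)
  x <- c(0.5, 0.1)
  expect_equal(trajectoryLoss(tr2, x),
               trajectoryLoss(methods::new("Trajectory",
                                           states = tr2@states[, 2:1],
                                           classLabel = 0L), x[2:1]))
})

test_that("decision score is antisymmetric under class-embedding swap", {
  m <- randomModel(n = 4, seed = 9)
  X <- matrix(runif(20), 5, 4)
  s <- decisionScore(m, X)
  m2 <- m
  m2@params$embed <- m@params$embed[, 2:1]
  expect_equal(decisionScore(m2, X), -s, tolerance = 1e-12)
  # identical embeddings for both classes collapse the score to zero
  m3 <- m
  m3@params$embed[, 2] <- m3@params$embed[, 1]
  expect_equal(decisionScore(m3, X), rep(0, 5), tolerance = 1e-12)
})

test_that("Youden threshold follows the midpoint convention", {
  expect_equal(selectThreshold(c(1, 2, 5, 6), c(0, 0, 1, 1)), 3.5)
  expect_equal(selectThreshold(c(0, 1), c(0, 1)), 0.5)
  expect_error(selectThreshold(c(1, 2), c(1, 1)), "both classes")
  # exhaustive-scan oracle on random instances
  set.seed(31)
  for (rep in 1:20) {
    sc <- round(runif(12), 2)
    lab <- sample(0:1, 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    th <- selectThreshold(sc, lab)
    J <- function(t) {
      pred <- as.integer(sc > t)
      mean(pred[lab == 1] == 1) + mean(pred[lab == 0] == 0) - 1
    }
    u <- sort(unique(sc))
    cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2)
    expect_equal(J(th), max(vapply(cand, J, numeric(1))), tolerance = 1e-12)
  }
})

test_that("labels independent of scores give near-zero maximal J", {
  set.seed(7)
  sc <- rnorm(4000)
  lab <- sample(0:1, 4000, replace = TRUE)
  th <- selectThreshold(sc, lab)
  pred <- as.integer(sc > th)
  J <- mean(pred[lab == 1] == 1) + mean(pred[lab == 0] == 0) - 1
  expect_lt(J, 0.1)
})

test_that("prediction uses a strict inequality and is monotone", {
  m <- randomModel()
  m@threshold <- 0.25
  X <- matrix(runif(40), 10, 4)
  sc <- decisionScore(m, X)
  expect_equal(predict(m, X), as.integer(sc > 0.25))
  # score exactly at the threshold maps to class 0
  m@threshold <- sc[1]
  expect_equal(predict(m, X)[1], 0L)
  n1 <- sum(predict(m, X, threshold = quantile(sc, 0.2)))
  n2 <- sum(predict(m, X, threshold = quantile(sc, 0.8)))
  expect_gte(n1, n2)
})
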