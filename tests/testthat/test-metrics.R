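test_that("confusion metrics follow their standard definitions", {
  m <- metricsFromConfusion(5, 5, 0, 0)
  expect_equal(unname(m["accuracy"]), 100)
  expect_equal(unname(m["f1"]), 100)
  expect_equal(unname(m["fpr"]), 0)
  m2 <- metricsFromConfusion(30, 20, 10, 40)
  expect_equal(unname(m2["accuracy"]), 50)
  expect_equal(unname(m2["precision"]), 75)
  expect_equal(unname(m2["recall"]), 100 * 30 / 70)
  expect_equal(unname(m2["fnr"]), 100 - unname(m2["recall"]))
  expect_equal(unname(m2["fpr"]), 100 - unname(m2["specificity"]))
  expect_warning(m3 <- metricsFromConfusion(0, 5, 0, 5), "precision")
  expect_equal(unname(m3["precision"]), 0)
  expect_error(metricsFromConfusion(0, 0, 0, 0), "all zero")
})

test_that("F1 is the harmonic mean of precision and recall in percent", {
  expect_equal(round(f1FromPrecisionRecall(93.61, 100), 2), 96.70)
  expect_equal(f1FromPrecisionRecall(0, 0), 0)
  expect_equal(f1FromPrecisionRecall(50, 50), 50)
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(rocAuc(c(10, 9), c(1, 0)), 1)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
  set.seed(19)
  for (n in 2:12) {
    for (rep in 1:8) {
      sc <- sample(round(runif(n), 1))  # ties likely
      lab <- sample(0:1, n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      expect_equal(rocAuc(sc, lab), aucPairOracle(sc, lab))
    }
  }
})

test_that("random scores give AUC near one half", {
  set.seed(2)
  sc <- rnorm(5000)
  lab <- sample(0:1, 5000, replace = TRUE)
  expect_equal(rocAuc(sc, lab), 0.5, tolerance = 0.03)
})

test_that("performance drop is plain subtraction in percentage points", {
  expect_equal(performanceDrop(97.77, 95.00), 2.77)
  expect_equal(performanceDrop(96.61, 92.00), 4.61)
  expect_equal(performanceDrop(80, 80), 0)
  expect_error(performanceDrop(101, 50))
})

test_that("group aggregation uses the population SD convention", {
  agg <- groupAggregate(c(96.61, 97.17))
  expect_equal(unname(agg["mean"]), 96.89)
  expect_equal(unname(agg["sd"]), 0.28)
  agg2 <- groupAggregate(c(83.73, 82.81, 84.13, 82.94))
  expect_equal(unname(agg2["mean"]), 83.40)
  expect_equal(unname(groupAggregate(42)["sd"]), 0)
  expect_error(groupAggregate(numeric()), "empty")
})

test_that("degenerate paired comparisons return p = 1 with warnings", {
  expect_warning(
    expect_warning(r <- reliabilityTests(c(1, 2, 3), c(1, 2, 3)),
                   "zero-variance"),
    "all paired differences")
  expect_equal(r["paired_t", "p"], 1)
  expect_equal(r["wilcoxon", "p"], 1)
})

test_that("constant-difference vectors hit the documented exact values", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  expect_warning(r <- reliabilityTests(a, b), "zero-variance")
  expect_equal(r["paired_t", "p"], 1)
  # all-negative signed ranks, n = 5: exact two-sided p = 2 / 2^5
  expect_equal(r["wilcoxon", "p"], 0.0625)
})

test_that("Mann-Whitney on fully separated triples matches enumeration", {
  r <- suppressWarnings(reliabilityTests(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r["mann_whitney", "statistic"], 0)
  expect_equal(r["mann_whitney", "p"], 0.1)
})

test_that("small-sample tests agree with brute-force enumeration", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    a <- round(runif(n), 2); b <- round(runif(n), 2)
    if (all(a == b)) next
    r <- suppressWarnings(reliabilityTests(a, b))
    # Wilcoxon signed-rank: enumerate all 2^m sign patterns over midranks
    d <- a - b; dnz <- d[d != 0]
    m <- length(dnz)
    if (m > 0) {
      rk <- rank(abs(dnz))
      v <- sum(rk[dnz > 0])
      vs <- vapply(0:(2^m - 1), function(code) {
        signs <- as.integer(intToBits(code))[1:m]
        sum(rk[signs == 1])
      }, numeric(1))
      pexp <- min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
      expect_equal(r["wilcoxon", "p"], pexp)
    }
    # Mann-Whitney: enumerate group assignments
    pooled <- rank(c(a, b))
    w <- sum(pooled[1:n])
    sums <- combn(pooled, n, sum)
    pexp <- min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
    expect_equal(r["mann_whitney", "p"], pexp)
  }
})
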