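makeCohort <- function(x, labels) {
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  colnames(x) <- paste0("g", seq_len(ncol(x)))
  ExpressionCohort(x, labels)
}

test_that("log2 fold change is the difference of group means", {
  x <- cbind(c(5, 5, 5, 8, 8, 8), c(2, 2, 2, 2, 2, 2))
  co <- makeCohort(x, c(0, 0, 0, 1, 1, 1))
  lfc <- log2FoldChange(co)
  expect_equal(unname(lfc), c(3, 0))

  set.seed(21)
  x <- matrix(rnorm(8 * 15), 8, 15)
  lab <- c(rep(0, 3), rep(1, 5))
  co <- makeCohort(x, lab)
  # brute-force two-loop oracle
  oracle <- numeric(15)
  for (g in 1:15) {
    m1 <- 0; m0 <- 0
    for (i in 1:8)
      if (lab[i] == 1) m1 <- m1 + x[i, g] / 5 else m0 <- m0 + x[i, g] / 3
    oracle[g] <- m1 - m0
  }
  expect_equal(unname(log2FoldChange(co)), oracle, tolerance = 1e-12)
})

test_that("single-class input is rejected as degenerate", {
  co <- makeCohort(matrix(rnorm(10), 5, 2), rep(1, 5))
  expect_error(log2FoldChange(co), "both classes")
})

test_that("two-sample t matches textbook pooled computation and t.test", {
  x <- rbind(c(1.1), c(2.0), c(2.9), c(5.1), c(6.0), c(6.9))
  co <- makeCohort(cbind(x, x + 1), c(0, 0, 0, 1, 1, 1))
  res <- twoSampleT(co, equalVar = TRUE)
  o <- pooledTOracle(c(5.1, 6.0, 6.9), c(1.1, 2.0, 2.9))
  expect_equal(res$t_stat[1], o$t, tolerance = 1e-9)
  expect_equal(res$p_raw[1], o$p, tolerance = 1e-9)
  tt <- t.test(c(5.1, 6.0, 6.9), c(1.1, 2.0, 2.9), var.equal = TRUE)
  expect_equal(res$p_raw[1], tt$p.value, tolerance = 1e-12)

  # Welch variant against stats::t.test
  set.seed(4)
  xm <- matrix(rnorm(12 * 4, sd = rep(c(1, 3), each = 6)), 12, 4)
  lab <- rep(c(0, 1), each = 6)
  cw <- makeCohort(xm, lab)
  rw <- twoSampleT(cw, equalVar = FALSE)
  for (g in 1:4) {
    tt <- t.test(xm[lab == 1, g], xm[lab == 0, g])
    expect_equal(rw$t_stat[g], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(rw$p_raw[g], tt$p.value, tolerance = 1e-9)
  }
})

test_that("identical groups give t = 0, p = 1", {
  co <- makeCohort(cbind(rep(4, 6), c(1, 2, 3, 1, 2, 3)),
                   c(0, 0, 0, 1, 1, 1))
  res <- twoSampleT(co)
  expect_equal(res$t_stat, c(0, 0))
  expect_equal(res$p_raw, c(1, 1))
})

test_that("fewer than two samples per class is an error", {
  co <- makeCohort(matrix(rnorm(6), 3, 2), c(0, 0, 1))
  expect_error(twoSampleT(co), ">= 2 samples")
})

test_that("BH adjustment equals the step-up definition exactly", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bhAdjust(0.37), 0.37)  # m = 1 is the identity
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(1:50, 1)
    p <- round(runif(n), 3)  # ties likely
    expect_equal(bhAdjust(p), bhStepUpOracle(p))
  }
  # permutation invariance: adjusted values follow their raw values
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output respects its structural invariants", {
  set.seed(12)
  p <- runif(40)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p - 1e-12))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
})

test_that("run_dea applies the conjunction rule and |log2FC| ranking", {
  sp <- cohortSpec(nControl = 50, nDiseased = 50, nGenes = 100, nDeg = 10,
                   effectLog2fc = 3, noiseSd = 0.5, seed = 17)
  co <- generateCohort(sp)
  deg <- runDEA(co)
  expect_true(all(deg$selected ==
                    (abs(deg$log2fc) >= 1.5 & deg$p_adj < 0.05)))
  expect_true(all(deg$p_adj >= deg$p_raw - 1e-12))
  sel <- deg[deg$selected, ]
  expect_setequal(sel$rank, seq_len(nrow(sel)))
  # ranks follow |log2FC| descending
  expect_true(all(diff(abs(sel$log2fc[order(sel$rank)])) <= 1e-12))
  # all planted genes recovered and dominating the top ranks
  expect_true(all(plantedGenes(co) %in% sel$gene_id))
  top <- sel$gene_id[order(sel$rank)][seq_along(plantedGenes(co))]
  expect_true(all(top %in% plantedGenes(co)))
  # volcano coordinates derivable per row
  expect_equal(deg$volcano_x, deg$log2fc)
  expect_equal(deg$volcano_y, -log10(pmax(deg$p_adj, .Machine$double.xmin)))
})

test_that("a large fold change with weak evidence is not selected", {
  # |log2FC| = 2 but high within-group spread at n = 3 per class: the
  # adjusted p stays far above alpha, so the conjunction rule rejects it
  x <- cbind(c(0, 2, 4, 2, 4, 6), rnorm(6, 8, 0.1))
  co <- makeCohort(x, c(0, 0, 0, 1, 1, 1))
  deg <- runDEA(co)
  expect_equal(deg$log2fc[1], 2)
  expect_gt(deg$p_adj[1], 0.05)
  expect_false(deg$selected[1])
  expect_true(is.na(deg$rank[1]))
})

test_that("under the global null the selected fraction stays below alpha", {
  fracs <- vapply(1:8, function(s) {
    co <- generateCohort(cohortSpec(nControl = 20, nDiseased = 20,
                                    nGenes = 80, nDeg = 0, noiseSd = 0.5,
                                    seed = s))
    deg <- runDEA(co)
    mean(deg$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
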