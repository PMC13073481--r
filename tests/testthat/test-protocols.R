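# Protocol plumbing is exercised with a fast nearest-centroid model; the
# full classifiers go through the same code path and are covered by the
# acceptance suite.

registerCentroidModel()

plantedCohort <- function(seed = 1, n = 30, genes = 40, deg = 6) {
  generateCohort(cohortSpec(nControl = n, nDiseased = n, nGenes = genes,
                            nDeg = deg, effectLog2fc = 3, noiseSd = 0.5,
                            seed = seed))
}

test_that("seen k-fold fits on training rows only and aggregates folds", {
  co <- plantedCohort()
  res <- runSeenKfold("centroid", co, k = 5, seed = 3)
  expect_s4_class(res, "ProtocolResult")
  expect_equal(nrow(res@perUnit), 5)
  expect_true(all(c("accuracy", "auc") %in% colnames(res@perUnit)))
  expect_true(isTRUE(auditLeakage(res)))
  expect_gte(protocolMean(res), 90)
  # deterministic given the seed
  res2 <- runSeenKfold("centroid", co, k = 5, seed = 3)
  expect_equal(res@perUnit, res2@perUnit)
})

test_that("degenerate fold counts that lose a class are rejected", {
  tiny <- generateCohort(cohortSpec(nControl = 2, nDiseased = 6,
                                    nGenes = 20, nDeg = 4, seed = 2))
  expect_error(runSeenKfold("centroid", tiny, k = 5, seed = 1),
               "lost a class")
})

test_that("unknown models are rejected with the registry listing", {
  co <- plantedCohort()
  expect_error(runSeenKfold("no-such-model", co, k = 2, seed = 1),
               "registered")
})

test_that("TT resubstitution bounds the seen k-fold accuracy from above", {
  co <- plantedCohort(seed = 5)
  tt <- runTT("centroid", co, seed = 3)
  seen <- runSeenKfold("centroid", co, k = 5, seed = 3)
  expect_gte(protocolMean(tt), protocolMean(seen) - 1e-9)
  expect_equal(tt@protocol, "tt")
  expect_true(is.na(tt@pd))
  expect_true(isTRUE(auditLeakage(tt)))
})

test_that("unseen evaluation harmonizes genes and attaches the drop", {
  sp <- cohortSpec(nControl = 30, nDiseased = 30, nGenes = 40, nDeg = 6,
                   effectLog2fc = 3, noiseSd = 0.5, seed = 7)
  pair <- generateCohortPair(sp, shiftSd = 0.3)
  seen <- runSeenKfold("centroid", pair$seen, k = 5, seed = 1)
  unseen <- runUnseen("centroid", pair$seen, pair$unseen, seed = 1,
                      seenResult = seen)
  expect_equal(unseen@protocol, "unseen")
  expect_false(is.na(unseen@pd))
  expect_equal(unseen@pd,
               protocolMean(seen) - unseen@perUnit$accuracy)
  expect_true(isTRUE(auditLeakage(unseen)))
  # identical cohorts: drop is zero up to fold noise
  unseen2 <- runUnseen("centroid", pair$seen, pair$seen, seed = 1,
                       seenResult = seen)
  expect_lt(abs(unseen2@pd), 10)
  # disjoint gene sets cannot be harmonized
  other <- plantedCohort(seed = 9)
  rownames(other) <- paste0("other_", rownames(other))
  expect_error(runUnseen("centroid", pair$seen, other, seed = 1),
               "no gene ids")
})

test_that("k-effect sweeps fold counts and includes the TT condition", {
  co <- plantedCohort(seed = 11)
  res <- runKEffect("centroid", co, ks = c(2L, 5L), seed = 2)
  expect_equal(nrow(res@perUnit), 3)
  expect_true(isTRUE(auditLeakage(res)))
})

test_that("fraction sweep evaluates a fixed held-out split", {
  co <- plantedCohort(seed = 13, n = 40)
  res <- runFractionSweep("centroid", co, fractions = c(0.2, 0.6, 1),
                          seed = 4)
  expect_equal(nrow(res@perUnit), 3)
  expect_true(isTRUE(auditLeakage(res)))
  # top fraction does at least as well as the smallest on planted signal
  acc <- res@perUnit$accuracy
  expect_gte(acc[3], acc[1] - 5)
  res2 <- runFractionSweep("centroid", co, fractions = c(0.2, 0.6, 1),
                           seed = 4)
  expect_equal(res@perUnit, res2@perUnit)
})

test_that("grid search reuses folds and prefers accuracy then simplicity", {
  co <- plantedCohort(seed = 15)
  gs <- gridSearch("centroid", list(dummy = c(1, 2)), co, k = 2, seed = 5)
  expect_equal(nrow(gs$table), 2)
  # same folds, model ignores the dummy parameter: identical accuracy,
  # tie broken by lattice order
  expect_equal(gs$table$meanAccuracy[1], gs$table$meanAccuracy[2])
  expect_equal(gs$best$dummy, 1)
  gs1 <- gridSearch("centroid", list(dummy = 7), co, k = 2, seed = 5)
  expect_equal(gs1$best$dummy, 7)
  expect_error(gridSearch("centroid", list(), co, k = 2, seed = 5),
               "empty grid")
})
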