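# Evaluation protocols: seen k-fold, total-train-test (TT), cross-cohort
# unseen, k-effect and training-fraction sweeps. Every fold fits DEA,
# min-max scaling and SMOTE on its training rows only; the audit trail in
# each ProtocolResult records the sample ids each fitted object saw so
# leakage is checkable after the fact.

metricNames <- c("accuracy", "precision", "recall", "specificity",
                 "fpr", "fnr", "f1", "auc")

# Stratified fold assignment: returns integer fold id per sample.
stratifiedFolds <- function(y, k, seed) {
  y <- as.integer(y)
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Fit the full leakage-safe pipeline on a training cohort:
# DEA -> min-max scaler -> SMOTE -> model.
fitPipeline <- function(modelName, train, seed, config = NULL,
                        deaArgs = list(), smoteK = 5L) {
  entry <- getModel(modelName)
  deg <- do.call(runDEA, c(list(train), deaArgs))
  genes <- selectedGenes(deg)
  if (length(genes) == 0L) {
    warning("no genes passed the DEA selection; falling back to the top ",
            "10 genes by |log2FC|")
    ord <- order(-abs(deg$log2fc), deg$gene_id)
    genes <- deg$gene_id[head(ord, min(10L, nrow(deg)))]
  }
  pre <- fitPreprocessor(train, genes)
  Xtr <- applyPreprocessor(pre, train)
  ytr <- cohortLabels(train)
  sm <- smoteOversample(Xtr, ytr, k = smoteK, seed = childSeed(seed, 7L))
  fit <- entry$fit(sm$X, sm$y, seed = childSeed(seed, 8L), config = config)
  list(modelName = modelName, deg = deg, genes = genes, pre = pre,
       fit = fit, entry = entry,
       audit = list(
         dea = S4Vectors::metadata(deg)$seenSamples,
         scaler = pre@seenSamples,
         smote = sampleIds(train),
         model = sampleIds(train)))
}

# Score + predict + metrics on a test cohort.
evaluatePipeline <- function(pipe, test) {
  Xte <- applyPreprocessor(pipe$pre, test)
  yte <- cohortLabels(test)
  scores <- pipe$entry$score(pipe$fit, Xte)
  pred <- as.integer(scores > fittedThreshold(pipe$fit))
  tp <- sum(pred == 1L & yte == 1L); tn <- sum(pred == 0L & yte == 0L)
  fp <- sum(pred == 1L & yte == 0L); fn <- sum(pred == 0L & yte == 1L)
  met <- suppressWarnings(metricsFromConfusion(tp, tn, fp, fn))
  auc <- if (length(unique(yte)) == 2L) rocAuc(scores, yte) else NA_real_
  c(met, auc = auc)
}

protocolResult <- function(protocol, perUnit, pd = NA_real_, audit = list()) {
  agg <- as.data.frame(lapply(perUnit[intersect(metricNames,
                                                colnames(perUnit))],
                              function(v) groupAggregate(v[is.finite(v)])))
  rownames(agg) <- c("mean", "sd")
  methods::new("ProtocolResult", protocol = protocol, perUnit = perUnit,
               aggregate = agg, pd = pd, audit = audit)
}

#' @describeIn runSeenKfold mean of a metric over folds/units.
#' @param result a \linkS4class{ProtocolResult}.
#' @param metric metric column name (default accuracy).
#' @export
protocolMean <- function(result, metric = "accuracy") {
  unname(result@aggregate["mean", metric])
}

#' Seen-paradigm stratified k-fold evaluation
#'
#' For each of k stratified folds: differential expression analysis,
#' min-max scaling and SMOTE are fitted on the training rows only, the
#' model is trained and the held-out fold scored. Metrics are aggregated
#' as mean and population SD across folds.
#'
#' @param modelName registry key (see [registeredModels()]).
#' @param data an \linkS4class{ExpressionCohort}.
#' @param k number of folds (>= 2).
#' @param seed RNG seed for fold assignment and every fit.
#' @param config optional model configuration list.
#' @param deaArgs optional arguments for [runDEA()].
#' @return A \linkS4class{ProtocolResult}.
#' @export
runSeenKfold <- function(modelName, data, k = 5L, seed = 1L, config = NULL,
                         deaArgs = list()) {
  stopifnot(k >= 2L)
  y <- cohortLabels(data)
  fold <- stratifiedFolds(y, k, childSeed(seed, 1L))
  rows <- list(); audit <- list()
  for (f in seq_len(k)) {
    train <- subsetSamples(data, which(fold != f))
    test <- subsetSamples(data, which(fold == f))
    ytr <- cohortLabels(train)
    if (min(table(factor(ytr, levels = 0:1))) < 2L ||
        length(unique(cohortLabels(test))) < 2L)
      stop("fold ", f, " lost a class after stratification; reduce k")
    pipe <- fitPipeline(modelName, train, childSeed(seed, 100L + f),
                        config = config, deaArgs = deaArgs)
    rows[[f]] <- data.frame(fold = f, t(evaluatePipeline(pipe, test)))
    audit[[paste0("fold", f)]] <- c(pipe$audit,
                                    list(testIds = sampleIds(test)))
  }
  protocolResult("seen_kfold", do.call(rbind, rows), audit = audit)
}

#' Total training-and-testing (TT) run
#'
#' Trains and tests on the full cohort (resubstitution); reported as a
#' memorization diagnostic, not a generalization estimate. The performance
#' drop field is absent (NA) by design.
#'
#' @inheritParams runSeenKfold
#' @return A \linkS4class{ProtocolResult} with protocol \code{"tt"}.
#' @export
runTT <- function(modelName, data, seed = 1L, config = NULL,
                  deaArgs = list()) {
  pipe <- fitPipeline(modelName, data, childSeed(seed, 2L), config = config,
                      deaArgs = deaArgs)
  row <- data.frame(fold = NA_integer_, t(evaluatePipeline(pipe, data)))
  protocolResult("tt", row,
                 audit = list(tt = c(pipe$audit,
                                     list(testIds = character()))))
}

#' Cross-cohort unseen evaluation
#'
#' Harmonizes features by gene-id intersection, fits the full pipeline on
#' the training cohort only (feature order follows the training DEA
#' ranking) and scores the independent test cohort. When a paired seen
#' result is supplied, the performance drop (seen minus unseen accuracy,
#' percentage points) is attached.
#'
#' @param modelName registry key.
#' @param trainCohort,testCohort \linkS4class{ExpressionCohort}s sharing at
#'   least one gene id.
#' @param seed RNG seed.
#' @param config optional model configuration list.
#' @param seenResult optional seen-paradigm \linkS4class{ProtocolResult} on
#'   \code{trainCohort} to compute the performance drop against.
#' @param deaArgs optional arguments for [runDEA()].
#' @return A \linkS4class{ProtocolResult} with protocol \code{"unseen"}.
#' @export
runUnseen <- function(modelName, trainCohort, testCohort, seed = 1L,
                      config = NULL, seenResult = NULL, deaArgs = list()) {
  shared <- intersect(geneIds(trainCohort), geneIds(testCohort))
  if (length(shared) == 0L)
    stop("cohorts share no gene ids; cannot harmonize features")
  tr <- methods::new("ExpressionCohort", trainCohort[shared, ])
  te <- methods::new("ExpressionCohort", testCohort[shared, ])
  pipe <- fitPipeline(modelName, tr, childSeed(seed, 3L), config = config,
                      deaArgs = deaArgs)
  row <- data.frame(fold = NA_integer_, t(evaluatePipeline(pipe, te)))
  pd <- if (!is.null(seenResult))
    performanceDrop(protocolMean(seenResult), row$accuracy) else NA_real_
  res <- protocolResult("unseen", row, pd = pd,
                        audit = list(unseen = c(pipe$audit,
                                                list(testIds = sampleIds(te)))))
  res
}

#' K-effect: seen evaluation across several fold counts
#'
#' Runs the seen k-fold protocol for each requested k plus the TT
#' (resubstitution) condition, collecting mean accuracy/AUC per setting.
#'
#' @inheritParams runSeenKfold
#' @param ks integer vector of fold counts.
#' @param includeTT also run the TT condition.
#' @return A \linkS4class{ProtocolResult} with protocol \code{"k_effect"};
#'   \code{perUnit} has one row per k (and one for TT).
#' @export
runKEffect <- function(modelName, data, ks = c(2L, 3L, 4L, 5L, 10L),
                       seed = 1L, config = NULL, includeTT = TRUE) {
  rows <- list(); audit <- list()
  for (k in ks) {
    r <- runSeenKfold(modelName, data, k = k, seed = seed, config = config)
    rows[[as.character(k)]] <-
      data.frame(k = k, accuracy = protocolMean(r),
                 auc = protocolMean(r, "auc"))
    audit[[paste0("k", k)]] <- r@audit
  }
  if (includeTT) {
    r <- runTT(modelName, data, seed = seed, config = config)
    rows[["tt"]] <- data.frame(k = NA_integer_,
                               accuracy = protocolMean(r),
                               auc = protocolMean(r, "auc"))
    audit[["tt"]] <- r@audit
  }
  protocolResult("k_effect", do.call(rbind, rows), audit = audit)
}

#' Memorization-vs-generalization training-fraction sweep
#'
#' Holds out a fixed stratified 20\% evaluation split, then trains on
#' stratified subsamples of the remaining data at each requested fraction
#' and evaluates on the fixed split, tracing accuracy/AUC against training
#' set size. Fractions leaving fewer than 2 samples per class are skipped
#' with a warning.
#'
#' @inheritParams runSeenKfold
#' @param fractions training fractions in (0, 1].
#' @return A \linkS4class{ProtocolResult} with protocol
#'   \code{"fraction_sweep"}.
#' @export
runFractionSweep <- function(modelName, data, fractions = seq(0.1, 1, 0.1),
                             seed = 1L, config = NULL) {
  y <- cohortLabels(data)
  fold <- stratifiedFolds(y, 5L, childSeed(seed, 4L))
  holdIdx <- which(fold == 1L)  # fixed 20% evaluation split
  trainPool <- which(fold != 1L)
  test <- subsetSamples(data, holdIdx)
  rows <- list(); audit <- list()
  for (fr in fractions) {
    take <- withSeed(childSeed(seed, 5L + round(fr * 100)), {
      unlist(lapply(c(0L, 1L), function(cl) {
        cand <- trainPool[y[trainPool] == cl]
        sample(cand, max(1L, round(length(cand) * fr)))
      }))
    })
    if (min(table(y[take])) < 2L || length(unique(y[take])) < 2L) {
      warning("fraction ", fr, " leaves < 2 samples in a class; skipped")
      next
    }
    train <- subsetSamples(data, sort(take))
    pipe <- fitPipeline(modelName, train,
                        childSeed(seed, 200L + round(fr * 100)),
                        config = config)
    rows[[as.character(fr)]] <-
      data.frame(fraction = fr, t(evaluatePipeline(pipe, test)))
    audit[[paste0("fraction", fr)]] <- c(pipe$audit,
                                         list(testIds = sampleIds(test)))
  }
  protocolResult("fraction_sweep", do.call(rbind, rows), audit = audit)
}

#' Exhaustive grid search with shared folds
#'
#' Evaluates every configuration on identical stratified folds via
#' [runSeenKfold()]; the best configuration has the highest mean accuracy,
#' ties broken by lower model complexity (parameter-count proxy from the
#' registry), then lattice order.
#'
#' @inheritParams runSeenKfold
#' @param grid named list of parameter value vectors (expanded to the full
#'   lattice).
#' @return List with \code{best} (configuration list), \code{table}
#'   (one row per configuration with mean accuracy) and \code{results}.
#' @export
gridSearch <- function(modelName, grid, data, k = 5L, seed = 1L) {
  if (length(grid) == 0L) stop("empty grid")
  lattice <- expand.grid(grid, stringsAsFactors = FALSE)
  entry <- getModel(modelName)
  results <- vector("list", nrow(lattice))
  rows <- vector("list", nrow(lattice))
  for (i in seq_len(nrow(lattice))) {
    config <- as.list(lattice[i, , drop = FALSE])
    names(config) <- colnames(lattice)
    r <- runSeenKfold(modelName, data, k = k, seed = seed, config = config)
    results[[i]] <- r
    rows[[i]] <- cbind(lattice[i, , drop = FALSE],
                       meanAccuracy = protocolMean(r),
                       complexity = entry$complexity(config))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$meanAccuracy, tab$complexity, seq_len(nrow(tab)))
  best <- as.list(lattice[ord[1], , drop = FALSE])
  names(best) <- colnames(lattice)
  list(best = best, table = tab, results = results)
}

#' Leakage audit of a protocol result
#'
#' Checks that no test-fold sample identifier appears among the samples
#' any fitted object (DEA, scaler, SMOTE, model) saw during fitting.
#'
#' @param result a \linkS4class{ProtocolResult}.
#' @return TRUE if the audit passes; otherwise a character vector naming
#'   the offending units.
#' @export
auditLeakage <- function(result) {
  bad <- character()
  for (unit in names(result@audit)) {
    a <- result@audit[[unit]]
    if (is.null(a$testIds)) {  # nested audits (k_effect)
      for (sub in names(a)) {
        s <- a[[sub]]
        seen <- unique(unlist(s[setdiff(names(s), "testIds")]))
        if (length(intersect(seen, s$testIds)))
          bad <- c(bad, paste0(unit, ".", sub))
      }
    } else {
      seen <- unique(unlist(a[setdiff(names(a), "testIds")]))
      if (length(intersect(seen, a$testIds))) bad <- c(bad, unit)
    }
  }
  if (length(bad)) bad else TRUE
}

setMethod("show", "ProtocolResult", function(object) {
  cat("ProtocolResult [", object@protocol, "]: ", nrow(object@perUnit),
      " unit(s)\n", sep = "")
  print(round(object@aggregate, 2))
  if (!is.na(object@pd))
    cat("performance drop (seen - unseen): ", round(object@pd, 2),
        " percentage points\n", sep = "")
})
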