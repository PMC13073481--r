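#' Fit a min-max preprocessor on a training fold
#'
#' Records per-gene minima and maxima over the training samples only, for a
#' fixed ordered gene list (typically the fold's selected DEGs). Constant
#' genes are recorded with max = min and later map to 0.
#'
#' @param train training-fold \linkS4class{ExpressionCohort}.
#' @param genes ordered character vector of gene ids to scale.
#' @return A \linkS4class{PreprocessState}.
#' @export
fitPreprocessor <- function(train, genes) {
  if (length(genes) == 0L) stop("gene list must be non-empty")
  missing <- setdiff(genes, geneIds(train))
  if (length(missing))
    stop("genes not present in training data: ",
         paste(head(missing, 5), collapse = ", "))
  x <- featureMatrix(train)[, genes, drop = FALSE]
  methods::new("PreprocessState",
               geneList = genes,
               geneMin = apply(x, 2, min),
               geneMax = apply(x, 2, max),
               labelMap = c(Control = 0L, Diseased = 1L),
               seenSamples = sampleIds(train))
}

#' Apply a fitted preprocessor
#'
#' Scales each listed gene by \code{(x - min) / (max - min)} with the
#' training-fold parameters and clips the result to [0, 1], so test values
#' outside the training range stay in the model's input domain. Constant
#' training genes (max = min) map to 0. The state itself is never updated.
#'
#' @param state a fitted \linkS4class{PreprocessState}.
#' @param cohort an \linkS4class{ExpressionCohort} to transform (training or
#'   test fold).
#' @return Numeric matrix, samples by selected genes, values in [0, 1].
#' @export
applyPreprocessor <- function(state, cohort) {
  if (!methods::is(state, "PreprocessState"))
    stop("usage error: 'state' must be a fitted PreprocessState")
  missing <- setdiff(state@geneList, geneIds(cohort))
  if (length(missing))
    stop("genes not present in data: ", paste(head(missing, 5), collapse = ", "))
  x <- featureMatrix(cohort)[, state@geneList, drop = FALSE]
  range <- state@geneMax - state@geneMin
  scaled <- sweep(x, 2, state@geneMin, "-")
  scaled <- sweep(scaled, 2, ifelse(range > 0, range, 1), "/")
  scaled[, range == 0] <- 0
  pmin(pmax(scaled, 0), 1)
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority oversampling: each synthetic row is
#' \code{x_i + u * (x_nn - x_i)} with \code{u ~ Uniform(0, 1)} and
#' \code{x_nn} one of the \code{k} nearest minority neighbours (Euclidean).
#' Original rows are preserved verbatim and classes are balanced to equal
#' counts. Intended to run on scaled training-fold features only.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y integer labels 0/1, one per row.
#' @param k neighbour count (reduced with a warning if it exceeds minority
#'   size - 1).
#' @param seed RNG seed.
#' @return List with balanced \code{X}, \code{y}, and \code{synthetic}
#'   (logical flag per row).
#' @export
smoteOversample <- function(X, y, k = 5L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (k < 1L) stop("invalid parameter: 'k' must be >= 1")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == n0)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  minority <- if (n1 < n0) 1L else 0L
  idx <- which(y == minority)
  if (length(idx) < 2L)
    stop("SMOTE needs a minority class of >= 2 samples (no neighbour available)")
  if (k > length(idx) - 1L) {
    warning("SMOTE k reduced from ", k, " to ", length(idx) - 1L,
            " (minority size ", length(idx), ")")
    k <- length(idx) - 1L
  }
  need <- abs(n1 - n0)
  Xm <- X[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1, function(r) order(r)[seq_len(k)]),
               nrow = length(idx), ncol = k, byrow = TRUE)
  synth <- withSeed(seed, {
    base <- sample(rep_len(seq_along(idx), need))
    pick <- vapply(base, function(b) nn[b, sample.int(k, 1L)], integer(1))
    u <- runif(need)
    Xm[base, , drop = FALSE] + u * (Xm[pick, , drop = FALSE] -
                                      Xm[base, , drop = FALSE])
  })
  if (!is.null(rownames(X)))
    rownames(synth) <- sprintf("smote_%03d", seq_len(need))
  else rownames(synth) <- NULL
  list(X = rbind(X, synth),
       y = c(y, rep(minority, need)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)))
}
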