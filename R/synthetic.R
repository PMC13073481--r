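#' Specification of a synthetic two-class expression cohort
#'
#' Describes a log2-scale two-class cohort with a planted set of
#' differentially expressed genes (DEGs). Planted genes receive a
#' between-group mean difference of \code{effectLog2fc} with alternating
#' sign (up-/down-regulated in the diseased group), all remaining genes
#' share the common baseline mean; every value carries independent Gaussian
#' noise. Defaults emulate a small microarray disease-vs-control study.
#'
#' @param nControl,nDiseased sample counts per class (>= 1).
#' @param nGenes number of genes (>= 1).
#' @param nDeg number of planted DEGs (0 allowed; <= nGenes).
#' @param effectLog2fc log2-fold-change magnitude of planted DEGs.
#' @param noiseSd per-value Gaussian SD on the log2 scale (> 0).
#' @param baselineMean common log2 expression baseline.
#' @param shiftSd per-gene cohort-offset SD used by [generateCohortPair()]
#'   (0 = no cross-cohort shift).
#' @param seed RNG seed; generation is a pure function of the spec.
#'
#' @return A list of class \code{"CohortSpec"}.
#' @examples
#' sp <- cohortSpec(nControl = 5, nDiseased = 5, nGenes = 10, nDeg = 2,
#'                  effectLog2fc = 3, noiseSd = 0.01, seed = 7)
#' generateCohort(sp)
#' @export
cohortSpec <- function(nControl = 100L, nDiseased = 100L, nGenes = 100L,
                       nDeg = 10L, effectLog2fc = 3.0, noiseSd = 0.5,
                       baselineMean = 8.0, shiftSd = 0.0, seed = 1L) {
  spec <- list(nControl = as.integer(nControl),
               nDiseased = as.integer(nDiseased),
               nGenes = as.integer(nGenes), nDeg = as.integer(nDeg),
               effectLog2fc = effectLog2fc, noiseSd = noiseSd,
               baselineMean = baselineMean, shiftSd = shiftSd,
               seed = as.integer(seed))
  for (f in c("nControl", "nDiseased", "nGenes"))
    if (is.na(spec[[f]]) || spec[[f]] < 1L)
      stop("invalid CohortSpec: '", f, "' must be >= 1")
  if (is.na(spec$nDeg) || spec$nDeg < 0L)
    stop("invalid CohortSpec: 'nDeg' must be >= 0")
  if (spec$nDeg > spec$nGenes)
    stop("invalid CohortSpec: 'nDeg' exceeds 'nGenes'")
  if (!is.finite(spec$noiseSd) || spec$noiseSd <= 0)
    stop("invalid CohortSpec: 'noiseSd' must be > 0")
  if (!is.finite(spec$shiftSd) || spec$shiftSd < 0)
    stop("invalid CohortSpec: 'shiftSd' must be >= 0")
  class(spec) <- "CohortSpec"
  spec
}

# Deterministic layout shared by both cohorts of a pair: planted gene
# positions and their alternating effect signs.
plantedLayout <- function(spec) {
  pos <- if (spec$nDeg > 0L)
    withSeed(childSeed(spec$seed, 1L), sample.int(spec$nGenes, spec$nDeg))
  else integer()
  sign <- rep_len(c(1, -1), length(pos))
  list(positions = pos, signs = sign)
}

# Draw one cohort given per-gene baselines and the planted layout.
drawCohort <- function(spec, baselines, layout, cohort, drawSeed) {
  n <- spec$nControl + spec$nDiseased
  labels <- c(rep(0L, spec$nControl), rep(1L, spec$nDiseased))
  geneNames <- sprintf("gene%05d", seq_len(spec$nGenes))
  mu <- matrix(baselines, nrow = n, ncol = spec$nGenes, byrow = TRUE)
  if (length(layout$positions))
    mu[labels == 1L, layout$positions] <- sweep(
      mu[labels == 1L, layout$positions, drop = FALSE], 2,
      layout$signs * spec$effectLog2fc, "+")
  noise <- withSeed(drawSeed,
    matrix(rnorm(n * spec$nGenes, sd = spec$noiseSd), n, spec$nGenes))
  x <- mu + noise
  rownames(x) <- sprintf("%s_s%03d", cohort, seq_len(n))
  colnames(x) <- geneNames
  ExpressionCohort(x, labels, cohort = cohort,
                   plantedGenes = geneNames[layout$positions])
}

#' Generate a synthetic two-class cohort
#'
#' @param spec a [cohortSpec()].
#' @return An \linkS4class{ExpressionCohort}; planted DEG identifiers are
#'   recorded in its metadata.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  drawCohort(spec, rep(spec$baselineMean, spec$nGenes), plantedLayout(spec),
             cohort = "A", drawSeed = childSeed(spec$seed, 2L))
}

#' Generate a cohort pair with cross-cohort covariate shift
#'
#' The two cohorts share gene identifiers and planted-DEG layout; the
#' second cohort's per-gene baselines are offset by independent
#' N(0, shiftSd^2) draws, emulating the distribution shift between two
#' independently collected studies.
#'
#' @param spec a [cohortSpec()].
#' @param shiftSd per-gene baseline offset SD (defaults to
#'   \code{spec$shiftSd}); must be >= 0.
#' @return List with elements \code{seen} and \code{unseen}, both
#'   \linkS4class{ExpressionCohort}s.
#' @export
generateCohortPair <- function(spec, shiftSd = spec$shiftSd) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (!is.finite(shiftSd) || shiftSd < 0)
    stop("invalid parameter: 'shiftSd' must be >= 0")
  layout <- plantedLayout(spec)
  baseA <- rep(spec$baselineMean, spec$nGenes)
  offset <- withSeed(childSeed(spec$seed, 3L),
                     rnorm(spec$nGenes, sd = shiftSd))
  a <- drawCohort(spec, baseA, layout, "A", childSeed(spec$seed, 2L))
  b <- drawCohort(spec, baseA + offset, layout, "B", childSeed(spec$seed, 4L))
  list(seen = a, unseen = b)
}
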