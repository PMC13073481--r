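#' Build an ExpressionCohort from a samples-by-genes matrix
#'
#' @param exprs numeric matrix, samples in rows, genes in columns, on log2
#'   scale. Row names are sample identifiers, column names gene identifiers
#'   (generated when absent).
#' @param labels integer/numeric vector of 0 (Control) / 1 (Diseased), one
#'   per sample.
#' @param cohort character tag naming the cohort.
#' @param plantedGenes optional character vector of planted differentially
#'   expressed genes (kept in metadata by the synthetic generator).
#'
#' @return An \linkS4class{ExpressionCohort}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("s", 1:4), paste0("g", 1:5)))
#' co <- ExpressionCohort(m, labels = c(0, 0, 1, 1))
#' dim(featureMatrix(co))
#' @export
ExpressionCohort <- function(exprs, labels, cohort = "cohort",
                             plantedGenes = character()) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("exprs must be a numeric matrix")
  if (length(labels) != nrow(exprs))
    stop("labels length (", length(labels), ") must equal sample count (",
         nrow(exprs), ")")
  if (is.null(rownames(exprs)))
    rownames(exprs) <- sprintf("sample%03d", seq_len(nrow(exprs)))
  if (is.null(colnames(exprs)))
    colnames(exprs) <- sprintf("gene%05d", seq_len(ncol(exprs)))
  labels <- as.integer(labels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = t(exprs)),
    colData = S4Vectors::DataFrame(label = labels, row.names = rownames(exprs)),
    metadata = list(cohort = cohort, plantedGenes = plantedGenes)
  )
  methods::new("ExpressionCohort", se)
}

#' @describeIn ExpressionCohort samples-by-genes numeric matrix view.
#' @param x an ExpressionCohort.
#' @export
featureMatrix <- function(x) {
  stopifnot(methods::is(x, "ExpressionCohort"))
  t(SummarizedExperiment::assay(x, "exprs"))
}

#' @describeIn ExpressionCohort integer label vector (0 = Control,
#'   1 = Diseased), named by sample.
#' @export
cohortLabels <- function(x) {
  stopifnot(methods::is(x, "ExpressionCohort"))
  setNames(SummarizedExperiment::colData(x)$label, colnames(x))
}

#' @describeIn ExpressionCohort gene identifiers (feature order).
#' @export
geneIds <- function(x) rownames(x)

#' @describeIn ExpressionCohort sample identifiers.
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn ExpressionCohort cohort tag.
#' @export
cohortName <- function(x) S4Vectors::metadata(x)$cohort

#' @describeIn ExpressionCohort planted differentially expressed genes
#'   (empty for real data).
#' @export
plantedGenes <- function(x) S4Vectors::metadata(x)$plantedGenes

# Subset a cohort to a set of samples (by id or index), keeping metadata.
subsetSamples <- function(x, samples) {
  y <- x[, samples]
  methods::new("ExpressionCohort", y)
}

setMethod("show", "ExpressionCohort", function(object) {
  lab <- SummarizedExperiment::colData(object)$label
  cat("ExpressionCohort '", cohortName(object), "': ",
      ncol(object), " samples x ", nrow(object), " genes (",
      sum(lab == 0L), " control / ", sum(lab == 1L), " diseased)\n",
      sep = "")
  if (length(plantedGenes(object)))
    cat("  planted DEGs:", length(plantedGenes(object)), "\n")
})
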