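#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
#' @importFrom stats pt rnorm runif sd t.test wilcox.test quantile setNames
#' @importFrom utils head read.delim write.csv modifyList combn
NULL

#' Two-class expression cohort
#'
#' Container for a sample-by-gene expression study with binary disease
#' labels, built on \linkS4class{SummarizedExperiment}. The assay
#' (\code{"exprs"}) is stored genes-in-rows following Bioconductor
#' convention; [featureMatrix()] returns the transposed samples-by-genes
#' view that the classifiers consume. Labels are coded 0 = Control,
#' 1 = Diseased.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; \code{colData} carries a
#'   \code{label} column and \code{metadata} a \code{cohort} tag plus, for
#'   synthetic cohorts, the identities of planted differentially expressed
#'   genes.
#'
#' @seealso [ExpressionCohort()], [generateCohort()]
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
  msg <- NULL
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!("label" %in% colnames(cd)))
    msg <- c(msg, "colData must contain a 'label' column")
  else {
    lab <- cd$label
    if (!all(lab %in% c(0L, 1L)))
      msg <- c(msg, "labels must be coded 0 (Control) / 1 (Diseased)")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(msg)) TRUE else msg
})

#' Fitted preprocessing state (min-max scaling over selected genes)
#'
#' Records, for a fixed ordered gene list, the per-gene minima and maxima
#' observed on the training fold, plus the label encoding. Applying the
#' state never mutates it; the sample identifiers it was fitted on are kept
#' for the leakage audit.
#'
#' @slot geneList ordered character vector of selected gene identifiers.
#' @slot geneMin,geneMax numeric vectors of per-gene training minima/maxima.
#' @slot labelMap named integer vector mapping class names to 0/1.
#' @slot seenSamples character vector of training sample identifiers.
#' @export
setClass("PreprocessState", representation(
  geneList = "character",
  geneMin = "numeric",
  geneMax = "numeric",
  labelMap = "integer",
  seenSamples = "character"
))

setValidity("PreprocessState", function(object) {
  msg <- NULL
  if (length(object@geneList) == 0L) msg <- c(msg, "geneList must be non-empty")
  if (length(object@geneMin) != length(object@geneList) ||
      length(object@geneMax) != length(object@geneList))
    msg <- c(msg, "min/max vectors must match geneList length")
  if (any(object@geneMax < object@geneMin))
    msg <- c(msg, "per-gene max must be >= min")
  if (is.null(msg)) TRUE else msg
})

#' Class-conditioned energy model
#'
#' Parameters of the energy-based generative classifier: an ELU multilayer
#' perceptron mapping gated features concatenated with a class embedding to
#' a scalar energy, learnable per-class prototypes, a trainable gene-gene
#' interaction matrix defining the residual force, and per-gene gate logits.
#'
#' @slot params list of parameter arrays (\code{W1,b1,W2,b2,w3,b3},
#'   \code{embed} (d_embed x 2), \code{gamma} (gate logits, length n),
#'   \code{proto} (n x 2 prototypes), \code{A} (n x n interaction matrix)).
#' @slot hyper list of hyperparameters (widths, dEmbed, nGenes).
#' @slot geneList gene identifiers the model was trained on (may be empty
#'   before training).
#' @slot trained logical flag.
#' @slot threshold decision threshold on the energy-difference score
#'   (NA before selection).
#' @slot seenSamples training sample identifiers (leakage audit).
#' @slot history per-epoch loss history data.frame.
#' @export
setClass("EnergyModel", representation(
  params = "list",
  hyper = "list",
  geneList = "character",
  trained = "logical",
  threshold = "numeric",
  seenSamples = "character",
  history = "data.frame"
))

#' Generated trajectory in feature space
#'
#' Ordered sequence of states produced by Runge-Kutta integration of the
#' model's vector field from a class prototype; the final state is the
#' generated sample.
#'
#' @slot states numeric matrix, (steps + 1) rows by n genes; row 1 is the
#'   starting state.
#' @slot classLabel integer class (0/1) the trajectory was conditioned on.
#' @export
setClass("Trajectory", representation(
  states = "matrix",
  classLabel = "integer"
))

setValidity("Trajectory", function(object) {
  if (nrow(object@states) < 2L) "a trajectory needs at least 2 states" else TRUE
})

#' Recurrent baseline classifier
#'
#' A gated recurrent classifier over chunked gene vectors: one or two
#' recurrent stages (unidirectional or bidirectional) built from classical,
#' cross-gated or exponential-gated LSTM cells, followed by dropout, a dense
#' layer and a sigmoid output unit.
#'
#' @slot spec list describing the architecture (cell kind, direction spec,
#'   units, dropout, timesteps, substreams, clamp).
#' @slot params list of stage/dense parameter arrays.
#' @slot trained logical flag.
#' @slot threshold probability cut for class 1.
#' @slot seenSamples training sample identifiers (leakage audit).
#' @export
setClass("RecurrentClassifier", representation(
  spec = "list",
  params = "list",
  trained = "logical",
  threshold = "numeric",
  seenSamples = "character"
))

#' Result of one evaluation protocol
#'
#' @slot protocol one of \code{"seen_kfold"}, \code{"tt"}, \code{"unseen"},
#'   \code{"k_effect"}, \code{"fraction_sweep"}.
#' @slot perUnit data.frame of per-fold (or per-fraction) metrics.
#' @slot aggregate data.frame with \code{mean} and population-\code{sd} rows.
#' @slot pd seen-minus-unseen accuracy difference in percentage points
#'   (NA where not applicable).
#' @slot audit list mapping fitted-object names to the sample identifiers
#'   each one saw during fitting.
#' @export
setClass("ProtocolResult", representation(
  protocol = "character",
  perUnit = "data.frame",
  aggregate = "data.frame",
  pd = "numeric",
  audit = "list"
))
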