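#' Per-gene log2 fold change
#'
#' Difference of log2 group means (diseased minus control) per gene. Input
#' is assumed to be on the log2 scale already; set \code{logTransform} to
#' apply \code{log2(x + 1)} first for raw-intensity matrices.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param logTransform apply \code{log2(x + 1)} before computing means.
#' @return Named numeric vector of signed log2 fold changes.
#' @export
log2FoldChange <- function(cohort, logTransform = FALSE) {
  x <- featureMatrix(cohort)
  if (logTransform) x <- log2(x + 1)
  lab <- cohortLabels(cohort)
  if (!any(lab == 0L) || !any(lab == 1L))
    stop("degenerate input: both classes must have at least one sample")
  colMeans(x[lab == 1L, , drop = FALSE]) -
    colMeans(x[lab == 0L, , drop = FALSE])
}

#' Per-gene two-sample t-test
#'
#' Vectorised two-sample t statistics and two-sided p-values per gene,
#' pooled-variance by default or Welch when \code{equalVar = FALSE}. Genes
#' with zero variance in both groups and equal means get t = 0, p = 1
#' (documented degenerate rule).
#'
#' @inheritParams log2FoldChange
#' @param equalVar pooled-variance test (default) vs Welch.
#' @return data.frame with columns \code{t_stat}, \code{p_raw}, one row per
#'   gene.
#' @export
twoSampleT <- function(cohort, equalVar = TRUE, logTransform = FALSE) {
  x <- featureMatrix(cohort)
  if (logTransform) x <- log2(x + 1)
  lab <- cohortLabels(cohort)
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("two-sample t-test needs >= 2 samples per class")
  x1 <- x[lab == 1L, , drop = FALSE]; x0 <- x[lab == 0L, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- apply(x1, 2, stats::var); v0 <- apply(x0, 2, stats::var)
  if (equalVar) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(se))
  } else {
    se2 <- v1 / n1 + v0 / n0
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups: equal means -> t = 0, p = 1; unequal
  # means -> infinite t, p = 0
  degenerate <- !is.finite(tstat) & (m1 - m0) == 0
  tstat[degenerate] <- 0
  p[degenerate] <- 1
  p[is.infinite(tstat)] <- 0
  data.frame(t_stat = tstat, p_raw = p, row.names = geneIds(cohort))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} with input
#' validation; returned in input order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values (FDR), same order as input.
#' @export
bhAdjust <- function(p) {
  stopIfNot01(p)
  stats::p.adjust(p, method = "BH")
}

#' Differential expression analysis
#'
#' Per-gene log2 fold change, two-sample t-test, Benjamini-Hochberg FDR
#' adjustment, selection by the conjunction rule
#' |log2FC| >= \code{lfcThreshold} AND adjusted p < \code{alpha}, and
#' ranking of selected genes by |log2FC| descending (ties broken by
#' lexicographic gene id). Volcano-plot coordinates (x = log2FC,
#' y = -log10 adjusted p) are included per row.
#'
#' @inheritParams twoSampleT
#' @param lfcThreshold absolute log2-fold-change selection threshold.
#' @param alpha FDR level for selection.
#' @return A \code{DFrame} (one row per gene) with columns \code{gene_id},
#'   \code{log2fc}, \code{t_stat}, \code{p_raw}, \code{p_adj},
#'   \code{selected}, \code{rank} (NA for unselected genes),
#'   \code{volcano_x}, \code{volcano_y}; metadata records thresholds and the
#'   sample ids used (leakage audit).
#' @export
runDEA <- function(cohort, lfcThreshold = 1.5, alpha = 0.05,
                   equalVar = TRUE, logTransform = FALSE) {
  if (!is.finite(lfcThreshold) || lfcThreshold < 0)
    stop("invalid parameter: 'lfcThreshold' must be >= 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("invalid parameter: 'alpha' must be in (0, 1]")
  lfc <- log2FoldChange(cohort, logTransform = logTransform)
  tt <- twoSampleT(cohort, equalVar = equalVar, logTransform = logTransform)
  padj <- bhAdjust(tt$p_raw)
  selected <- abs(lfc) >= lfcThreshold & padj < alpha
  ids <- geneIds(cohort)
  rank <- rep(NA_integer_, length(ids))
  if (any(selected)) {
    sel <- which(selected)
    ord <- sel[order(-abs(lfc[sel]), ids[sel])]
    rank[ord] <- seq_along(ord)
  }
  out <- S4Vectors::DataFrame(
    gene_id = ids, log2fc = unname(lfc), t_stat = tt$t_stat,
    p_raw = tt$p_raw, p_adj = padj, selected = unname(selected),
    rank = rank, volcano_x = unname(lfc),
    volcano_y = -log10(pmax(padj, .Machine$double.xmin)),
    row.names = ids)
  S4Vectors::metadata(out) <- list(
    lfcThreshold = lfcThreshold, alpha = alpha,
    seenSamples = sampleIds(cohort))
  out
}

#' Selected genes of a DEA table in rank order
#'
#' @param deg a table from [runDEA()].
#' @return Character vector of selected gene ids, best (largest |log2FC|)
#'   first.
#' @export
selectedGenes <- function(deg) {
  sel <- deg[!is.na(deg$rank), , drop = FALSE]
  sel$gene_id[order(sel$rank)]
}

#' Write a DEA table as TSV (and volcano coordinates as CSV)
#'
#' @param deg a table from [runDEA()].
#' @param path output TSV path.
#' @param volcanoPath optional CSV path for volcano coordinates.
#' @return Invisibly, the TSV path.
#' @export
writeDEGTable <- function(deg, path, volcanoPath = NULL) {
  df <- as.data.frame(deg)[, c("gene_id", "log2fc", "t_stat", "p_raw",
                               "p_adj", "selected", "rank")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(volcanoPath))
    write.csv(as.data.frame(deg)[, c("gene_id", "volcano_x", "volcano_y")],
              volcanoPath, row.names = FALSE)
  invisible(path)
}
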