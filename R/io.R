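# Delimited-text input/output for cohorts, model checkpoints and report
# bundles. The on-disk cohort layout matches the synthetic generator:
# sample id in column 1, 0/1 label in column 2, one column per gene.

#' Write an ExpressionCohort as delimited text
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param path output path (TSV).
#' @return Invisibly, the path.
#' @export
writeExpressionMatrix <- function(cohort, path) {
  df <- data.frame(sample_id = sampleIds(cohort),
                   label = unname(cohortLabels(cohort)),
                   featureMatrix(cohort), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with labels from delimited text
#'
#' Accepts tab- or comma-delimited files (auto-detected), samples-in-rows
#' (default) or genes-in-rows layout, with a sample-id column and a binary
#' label column. Values are expected on log2 scale (see
#' \code{logTransform} in [runDEA()] otherwise).
#'
#' @param path file path.
#' @param orientation \code{"samples"} (rows are samples) or
#'   \code{"genes"} (rows are genes; the label row is named by
#'   \code{labelColumn}).
#' @param labelColumn name of the label column (or row).
#' @param cohort cohort tag to attach.
#' @return An \linkS4class{ExpressionCohort}.
#' @export
readExpressionMatrix <- function(path, orientation = c("samples", "genes"),
                                 labelColumn = "label", cohort = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (orientation == "genes") {
    ids <- df[[1]]
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- ids
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  }
  if (!(labelColumn %in% colnames(df)))
    stop("label column '", labelColumn, "' not found in ", path)
  idCol <- colnames(df)[1]
  geneCols <- colnames(df)[!(colnames(df) %in% c(idCol, labelColumn))]
  dup <- unique(geneCols[duplicated(geneCols)])
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  x <- as.matrix(df[, geneCols, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(x), nrow(x)))) & !is.na(x), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at row ", bad[1], ", gene '",
         geneCols[bad[2]], "'")
  }
  lab <- df[[labelColumn]]
  if (!all(lab %in% c(0, 1)))
    stop("labels must be coded 0/1 in column '", labelColumn, "'")
  rownames(x) <- as.character(df[[idCol]])
  ExpressionCohort(x, as.integer(lab),
                   cohort = cohort %||na% basename(path))
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an energy model checkpoint as JSON
#'
#' The checkpoint is a single JSON document: a \code{hyper} block plus a
#' flat named list of parameter arrays (with dimensions), the gene list
#' and the decision threshold.
#'
#' @param model an \linkS4class{EnergyModel}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeEnergyModel <- function(model, path) {
  flat <- lapply(model@params, function(x)
    list(dim = if (is.matrix(x)) dim(x) else length(x), data = as.numeric(x)))
  jsonlite::write_json(
    list(hyper = model@hyper, params = flat, geneList = model@geneList,
         threshold = model@threshold, trained = model@trained),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn writeEnergyModel restore a checkpoint.
#' @export
readEnergyModel <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ck$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  model <- initEnergyModel(ck$hyper$nGenes, ck$hyper$widths, ck$hyper$dEmbed)
  model@params <- params
  model@geneList <- as.character(ck$geneList)
  model@threshold <- as.numeric(ck$threshold)
  model@trained <- isTRUE(ck$trained)
  model
}

#' Write a report bundle for a protocol result
#'
#' Emits a metrics CSV mirroring the benchmark table column order (ACCU,
#' PREC, REC, FS, AUC, plus PD when defined), a full-precision JSON
#' report, the DEG TSV and volcano CSV, the training loss history and the
#' leakage-audit log. Filenames are fixed; re-running with identical
#' inputs reproduces the files byte for byte.
#'
#' @param result a \linkS4class{ProtocolResult}.
#' @param deg optional DEA table from [runDEA()].
#' @param dir output directory (created if needed).
#' @param lossHistory optional loss-history data.frame.
#' @param config optional fully-resolved run configuration to record.
#' @return Invisibly, the directory.
#' @export
writeReports <- function(result, deg = NULL, dir = ".", lossHistory = NULL,
                         config = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  cols <- c("accuracy", "precision", "recall", "f1", "auc")
  present <- intersect(cols, colnames(result@perUnit))
  tab <- result@perUnit[, c(setdiff(colnames(result@perUnit),
                                    metricNames), present)]
  colMap <- c(accuracy = "ACCU", precision = "PREC", recall = "REC",
              f1 = "FS", auc = "AUC")
  names(tab)[match(present, names(tab))] <- colMap[present]
  if (!is.na(result@pd)) tab$PD <- c(result@pd, rep(NA, nrow(tab) - 1L))
  write.csv(format(tab, digits = 8), file.path(dir, "metrics_table.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(protocol = result@protocol, perUnit = result@perUnit,
         aggregate = cbind(stat = rownames(result@aggregate),
                           result@aggregate),
         pd = result@pd),
    file.path(dir, "metrics_full.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  if (!is.null(deg))
    writeDEGTable(deg, file.path(dir, "deg_table.tsv"),
                  volcanoPath = file.path(dir, "volcano.csv"))
  if (!is.null(lossHistory))
    write.csv(lossHistory, file.path(dir, "loss_history.csv"),
              row.names = FALSE)
  jsonlite::write_json(result@audit, file.path(dir, "audit_log.json"),
                       auto_unbox = TRUE)
  if (!is.null(config))
    jsonlite::write_json(config, file.path(dir, "config_resolved.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
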