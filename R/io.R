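#' Read and write pipeline artifacts
#'
#' Fixed file contracts for the pipeline: the expression matrix as TSV with
#' samples in rows and a leading \code{sample_id} column; sample metadata as
#' a two-column TSV (\code{sample_id}, \code{cohort}); per-well amplification
#' curves as a long TSV (\code{well_id}, \code{marker_id}, \code{role},
#' \code{cycle}, \code{fluorescence}); fitted models and evaluation results
#' as JSON. Every writer's output is re-readable by the matching reader.
#'
#' @param se a \linkS4class{SummarizedExperiment} (markers in rows).
#' @param path file path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeExpressionTSV <- function(se, path) {
  x <- t(SummarizedExperiment::assay(se))
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @return \code{readExpressionTSV}: samples-by-markers numeric matrix.
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' @rdname pipeline-io
#' @param design data.frame with \code{sample_id} and \code{cohort}.
#' @export
writeMetadataTSV <- function(design, path) {
  utils::write.table(design[, c("sample_id", "cohort")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readMetadataTSV <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  df$cohort <- factor(df$cohort,
                      levels = intersect(c("HC", "PS", "SEPSIS", "MI"),
                                         unique(df$cohort)))
  df
}

#' @rdname pipeline-io
#' @param matrixPath,metadataPath paths to a matrix TSV and metadata TSV.
#' @return \code{readExpressionSE}: a SummarizedExperiment combining matrix
#'   and metadata.
#' @export
readExpressionSE <- function(matrixPath, metadataPath) {
  m <- readExpressionTSV(matrixPath)
  meta <- readMetadataTSV(metadataPath)
  if (!identical(sort(meta$sample_id), sort(rownames(m))))
    stop("metadata samples do not match the expression matrix")
  meta <- meta[match(rownames(m), meta$sample_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2fc = t(m)),
    colData = S4Vectors::DataFrame(cohort = meta$cohort,
                                   row.names = meta$sample_id))
}

#' @rdname pipeline-io
#' @param curves long curve data.frame.
#' @export
writeCurveTSV <- function(curves, path) {
  utils::write.table(curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readCurveTSV <- function(path) {
  utils::read.delim(path, colClasses = c(well_id = "character",
                                         marker_id = "character",
                                         role = "character"))
}

#' @rdname pipeline-io
#' @param model a [LogitBoostModel-class].
#' @export
writeModelJSON <- function(model, path) {
  jsonlite::write_json(
    list(stumps = data.frame(
           feature = model@featureNames[model@stumps$feature],
           threshold = model@stumps$threshold,
           left = model@stumps$left,
           right = model@stumps$right),
         featureNames = model@featureNames,
         classLabels = model@classLabels,
         M = model@M, zMax = model@zMax, negLogLik = model@negLogLik),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readModelJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- if (length(j$stumps))
    data.frame(feature = match(j$stumps$feature, j$featureNames),
               threshold = j$stumps$threshold,
               left = j$stumps$left, right = j$stumps$right)
  else
    data.frame(feature = integer(), threshold = numeric(),
               left = numeric(), right = numeric())
  new("LogitBoostModel", stumps = st, featureNames = j$featureNames,
      classLabels = j$classLabels, M = as.integer(j$M), zMax = j$zMax,
      negLogLik = j$negLogLik)
}

#' @rdname pipeline-io
#' @param result an [EvaluationResult-class].
#' @export
writeResultJSON <- function(result, path) {
  jsonlite::write_json(
    list(comparison = result@comparison, panelSize = result@panelSize,
         auc = result@auc, nullAuc = result@nullAuc,
         pValue = result@pValue, seed = result@seed),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readResultJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EvaluationResult", comparison = j$comparison,
      panelSize = as.integer(j$panelSize),
      auc = as.numeric(j$auc %||% numeric()),
      nullAuc = as.numeric(j$nullAuc %||% numeric()),
      pValue = if (is.null(j$pValue)) NA_real_ else j$pValue,
      seed = as.integer(j$seed %||% NA_integer_))
}
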