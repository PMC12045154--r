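#' @rdname ExpressionDataset
#' @export
setMethod("geneNames", "ExpressionDataset", function(x) rownames(x))

#' @rdname ExpressionDataset
#' @export
setMethod("obsIds", "ExpressionDataset", function(x) colnames(x))

#' @rdname ExpressionDataset
#' @export
setMethod("cellLabels", "ExpressionDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("cell_type" %in% colnames(cd)) as.character(cd$cell_type) else NULL
})

#' @rdname ExpressionDataset
#' @export
setMethod("spatialCoords", "ExpressionDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("x", "y") %in% colnames(cd))) return(NULL)
  cbind(x = as.numeric(cd$x), y = as.numeric(cd$y))
})

#' @rdname ExpressionDataset
#' @export
setMethod("layerTag", "ExpressionDataset",
          function(x) S4Vectors::metadata(x)$layer_tag)

#' @rdname ExpressionDataset
#' @export
setMethod("exprValues", "ExpressionDataset",
          function(x) SummarizedExperiment::assay(x, 1L))

setMethod("show", "ExpressionDataset", function(object) {
  cat(sprintf("ExpressionDataset: %d genes x %d observations [%s]\n",
              nrow(object), ncol(object), layerTag(object)))
  if (!is.null(cellLabels(object)))
    cat(sprintf("  labels: %d cell types\n",
                length(unique(cellLabels(object)))))
  if (!is.null(spatialCoords(object)))
    cat("  spatial coordinates: yes\n")
  invisible(NULL)
})

#' @rdname GeneScoreTable
#' @export
setMethod("genePanel", "GeneScoreTable", function(x) x@panel)

#' @rdname GeneScoreTable
#' @export
setMethod("attentionWeights", "GeneScoreTable", function(x) x@attention)

#' @rdname GeneScoreTable
#' @export
setMethod("typeVocabulary", "GeneScoreTable", function(x) colnames(x@lambda))

setMethod("show", "GeneScoreTable", function(object) {
  cat(sprintf("GeneScoreTable: %d genes x %d cell types (mu = %g)\n",
              nrow(object@lambda), ncol(object@lambda), object@mu))
  cat(sprintf("  panel: %d genes (%s, nTop = %d)\n", length(object@panel),
              if (object@perType) "per type" else "global", object@nTop))
  invisible(NULL)
})

#' Long-format view of a GeneScoreTable
#'
#' @param x a `GeneScoreTable`.
#' @param row.names,optional,... passed for generic compatibility; unused.
#' @return data.frame with columns `gene`, `cell_type`, `lambda`,
#'   `cosg_score`, `attention_weight`, `fused_score`.
#' @export
as.data.frame.GeneScoreTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  g <- rownames(x@lambda)
  k <- colnames(x@lambda)
  data.frame(
    gene = rep(g, times = length(k)),
    cell_type = rep(k, each = length(g)),
    lambda = as.vector(x@lambda),
    cosg_score = as.vector(x@cosg),
    attention_weight = rep(unname(x@attention), times = length(k)),
    fused_score = as.vector(x@fused),
    stringsAsFactors = FALSE)
}

#' @rdname CellTypeProbabilityMatrix
#' @export
setMethod("probValues", "CellTypeProbabilityMatrix", function(x) x@probs)

#' @rdname CellTypeProbabilityMatrix
#' @export
setMethod("typeVocabulary", "CellTypeProbabilityMatrix",
          function(x) colnames(x@probs))

#' @rdname CellTypeProbabilityMatrix
#' @export
setMethod("obsIds", "CellTypeProbabilityMatrix",
          function(x) rownames(x@probs))

setMethod("show", "CellTypeProbabilityMatrix", function(object) {
  cat(sprintf("CellTypeProbabilityMatrix: %d observations x %d cell types\n",
              nrow(object@probs), ncol(object@probs)))
  invisible(NULL)
})

#' @rdname TrainedClassifier
#' @param x,object a `TrainedClassifier`.
#' @export
setMethod("genePanel", "TrainedClassifier", function(x) x@panel)

#' @rdname TrainedClassifier
#' @export
setMethod("typeVocabulary", "TrainedClassifier", function(x) x@vocabulary)

#' Per-epoch training history
#'
#' @param x a `TrainedClassifier`.
#' @return data.frame with one row per epoch: `epoch`, `trainLoss`,
#'   `trainAccuracy`, `valLoss`, `valAccuracy`.
#' @export
trainHistory <- function(x) {
  stopifnot(is(x, "TrainedClassifier"))
  x@history
}

setMethod("show", "TrainedClassifier", function(object) {
  s <- object@networkSpec
  cat(sprintf(
    "TrainedClassifier: %d panel genes -> (%s) -> %d cell types\n",
    s$inputDim, paste(s$hiddenDims, collapse = ","), s$outputDim))
  cat(sprintf("  residual: hidden %d -> hidden %d; trained %d epochs\n",
              s$residual[1L], s$residual[2L], nrow(object@history)))
  invisible(NULL)
})

#' @rdname ReferenceMap
#' @export
setMethod("mapValues", "ReferenceMap", function(x) x@values)

#' @rdname ReferenceMap
#' @export
setMethod("typeVocabulary", "ReferenceMap", function(x) colnames(x@values))

setMethod("show", "ReferenceMap", function(object) {
  cat(sprintf("ReferenceMap (%s): %d observations x %d cell types\n",
              object@source, nrow(object@values), ncol(object@values)))
  invisible(NULL)
})

#' @rdname EvaluationReport
#' @export
setMethod("accScores", "EvaluationReport", function(x) x@accScore)

#' @rdname EvaluationReport
#' @export
setMethod("metricValues", "EvaluationReport", function(x) x@values)

#' @rdname EvaluationReport
#' @export
setMethod("metricRanks", "EvaluationReport", function(x) x@ranks)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d methods, metrics: %s\n",
              nrow(object@values), paste(colnames(object@values),
                                         collapse = ", ")))
  sc <- sort(object@accScore, decreasing = TRUE)
  for (m in names(sc))
    cat(sprintf("  %-20s Acc Score %.3f\n", m, sc[[m]]))
  invisible(NULL)
})
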