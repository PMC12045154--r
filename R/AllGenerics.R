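#' @rdname ExpressionDataset
#' @param x,object an `ExpressionDataset` (or other DSCT object for `show`).
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname ExpressionDataset
#' @export
setGeneric("obsIds", function(x) standardGeneric("obsIds"))

#' @rdname ExpressionDataset
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname ExpressionDataset
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname ExpressionDataset
#' @export
setGeneric("layerTag", function(x) standardGeneric("layerTag"))

#' @rdname ExpressionDataset
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname CellTypeProbabilityMatrix
#' @param x a DSCT object with a cell-type vocabulary.
#' @export
setGeneric("typeVocabulary", function(x) standardGeneric("typeVocabulary"))

#' @rdname CellTypeProbabilityMatrix
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))

#' @rdname GeneScoreTable
#' @param x a `GeneScoreTable` or `TrainedClassifier`.
#' @export
setGeneric("genePanel", function(x) standardGeneric("genePanel"))

#' @rdname GeneScoreTable
#' @export
setGeneric("attentionWeights", function(x) standardGeneric("attentionWeights"))

#' @rdname ReferenceMap
#' @param x a `ReferenceMap` or `EvaluationReport`.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname EvaluationReport
#' @param x an `EvaluationReport`.
#' @export
setGeneric("accScores", function(x) standardGeneric("accScores"))

#' @rdname EvaluationReport
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname EvaluationReport
#' @export
setGeneric("metricRanks", function(x) standardGeneric("metricRanks"))
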