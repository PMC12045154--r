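#' ExpressionDataset: expression matrix with gene and observation annotation
#'
#' The common currency of the DSCT workflow: a genes x observations
#' expression matrix (raw counts or normalized values) held in a
#' [SummarizedExperiment::SummarizedExperiment] together with optional
#' per-observation cell-type labels (`colData` column `cell_type`) and 2-D
#' spatial coordinates (`colData` columns `x`, `y`). The layer tag
#' (`"raw"` or `"normalized"`) is stored in `metadata(x)$layer_tag`; raw
#' data must be non-negative integers.
#'
#' @param counts numeric matrix (dense or `Matrix` sparse), genes as rows
#'   with unique rownames, observations as columns with unique colnames.
#' @param labels optional character vector of per-observation cell types.
#' @param coords optional numeric matrix/data.frame with two columns (x, y)
#'   and one row per observation.
#' @param layerTag `"raw"` (integer counts) or `"normalized"`.
#'
#' @return An `ExpressionDataset`.
#' @examples
#' m <- matrix(rpois(12, 4), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' ds <- ExpressionDataset(m, labels = c("a", "a", "b", "b"))
#' geneNames(ds)
#' @export
ExpressionDataset <- function(counts, labels = NULL, coords = NULL,
                              layerTag = c("raw", "normalized")) {
  layerTag <- match.arg(layerTag)
  if (is.null(dim(counts)))
    .stopf("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("'counts' must carry gene names (rownames) and observation ids (colnames)")
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(labels)) {
    if (length(labels) != ncol(counts))
      .stopf("length of 'labels' (%d) does not match observation count (%d)",
             length(labels), ncol(counts))
    cd$cell_type <- as.character(labels)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (ncol(coords) != 2L || nrow(coords) != ncol(counts))
      .stopf("'coords' must have two columns and one row per observation")
    cd$x <- as.numeric(coords[, 1L])
    cd$y <- as.numeric(coords[, 2L])
  }
  assayName <- if (layerTag == "raw") "counts" else "logcounts"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(counts), assayName),
    colData = cd)
  S4Vectors::metadata(se)$layer_tag <- layerTag
  out <- new("ExpressionDataset", se)
  validObject(out)
  out
}

#' @rdname ExpressionDataset
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return("no assay present")
  m <- SummarizedExperiment::assay(object, 1L)
  gn <- rownames(object)
  ob <- colnames(object)
  if (is.null(gn) || anyDuplicated(gn))
    msg <- c(msg, "gene names must be present and unique")
  if (is.null(ob) || anyDuplicated(ob))
    msg <- c(msg, "observation ids must be present and unique")
  vals <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(vals) && (anyNA(vals) || any(!is.finite(vals))))
    msg <- c(msg, "matrix entries must be finite")
  else if (length(vals) && any(vals < 0))
    msg <- c(msg, "matrix entries must be non-negative")
  tag <- S4Vectors::metadata(object)$layer_tag
  if (is.null(tag) || !tag %in% c("raw", "normalized"))
    msg <- c(msg, "metadata layer_tag must be 'raw' or 'normalized'")
  else if (tag == "raw" && length(vals) && !.isWholeNumber(vals))
    msg <- c(msg, "raw data must contain integer counts")
  if (length(msg)) msg else TRUE
})

#' GeneScoreTable: per-(gene, cell type) marker scores
#'
#' Holds the penalized cosine marker scores and the attention fusion that
#' drive feature-gene selection: the cosine similarity `lambda` between
#' each gene's expression and each cell-type indicator, the penalized COSG
#' score, the per-gene attention weight (non-negative, summing to one over
#' genes), the fused ACOSG score and the selected panel.
#'
#' @slot lambda genes x types matrix of cosine similarities in \[-1, 1\].
#' @slot cosg genes x types matrix of penalized cosine (COSG) scores.
#' @slot attention named per-gene non-negative weights summing to 1.
#' @slot fused genes x types matrix of attention-fused scores.
#' @slot mu penalty hyper-parameter (>= 0).
#' @slot nTop requested panel size per type (or globally).
#' @slot perType whether selection was per cell type.
#' @slot panel selected gene names, in reference gene order.
#' @export
setClass("GeneScoreTable",
  representation(lambda = "matrix", cosg = "matrix", attention = "numeric",
                 fused = "matrix", mu = "numeric", nTop = "integer",
                 perType = "logical", panel = "character"))

setValidity("GeneScoreTable", function(object) {
  msg <- character()
  d <- dim(object@lambda)
  if (!identical(dim(object@cosg), d) || !identical(dim(object@fused), d))
    msg <- c(msg, "lambda, cosg and fused must share dimensions")
  if (length(object@attention) != d[1L])
    msg <- c(msg, "attention must have one weight per gene")
  if (length(object@attention) &&
      abs(sum(object@attention) - 1) > 1e-6)
    msg <- c(msg, "attention weights must sum to 1")
  if (any(object@attention < 0))
    msg <- c(msg, "attention weights must be non-negative")
  if (length(object@lambda) && max(abs(object@lambda)) > 1 + 1e-8)
    msg <- c(msg, "lambda must lie in [-1, 1]")
  if (length(object@cosg) && max(abs(object@cosg)) > 1 + 1e-8)
    msg <- c(msg, "cosg scores must lie in [-1, 1]")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (!all(object@panel %in% rownames(object@lambda)))
    msg <- c(msg, "panel genes must appear in the score matrices")
  if (length(msg)) msg else TRUE
})

#' TrainedClassifier: fitted residual MLP with its gene panel and vocabulary
#'
#' @slot networkSpec list describing the architecture (see [buildNetwork()]).
#' @slot weights list of layer weight matrices and bias vectors.
#' @slot panel ordered gene names the network was trained on.
#' @slot vocabulary ordered cell-type names (output classes).
#' @slot geneCenter,geneScale per-panel-gene standardization statistics
#'   estimated on the reference and re-applied at prediction time.
#' @slot history per-epoch training/validation loss and accuracy.
#' @slot trainingConfig list of the training hyper-parameters used.
#' @export
setClass("TrainedClassifier",
  representation(networkSpec = "list", weights = "list", panel = "character",
                 vocabulary = "character", geneCenter = "numeric",
                 geneScale = "numeric", history = "data.frame",
                 trainingConfig = "list"))

setValidity("TrainedClassifier", function(object) {
  msg <- character()
  if (length(object@panel) != object@networkSpec$inputDim)
    msg <- c(msg, "panel length must equal the network input dimension")
  if (length(object@vocabulary) != object@networkSpec$outputDim)
    msg <- c(msg, "vocabulary size must equal the network output dimension")
  if (length(object@geneCenter) != length(object@panel) ||
      length(object@geneScale) != length(object@panel))
    msg <- c(msg, "standardization statistics must match the panel")
  if (length(msg)) msg else TRUE
})

#' CellTypeProbabilityMatrix: observations x cell types on the simplex
#'
#' The primary DSCT output: each row is a probability distribution over the
#' label vocabulary for one spatial observation.
#'
#' @param probs numeric matrix, observations as rows (rownames = ids),
#'   cell types as columns (colnames = vocabulary); rows must sum to 1.
#' @return A `CellTypeProbabilityMatrix`.
#' @export
CellTypeProbabilityMatrix <- function(probs) {
  out <- new("CellTypeProbabilityMatrix", probs = as.matrix(probs))
  validObject(out)
  out
}

#' @rdname CellTypeProbabilityMatrix
#' @export
setClass("CellTypeProbabilityMatrix", representation(probs = "matrix"))

setValidity("CellTypeProbabilityMatrix", function(object) {
  m <- object@probs
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "probability matrix needs observation ids and cell-type names")
  if (length(m)) {
    if (anyNA(m) || min(m) < -1e-9 || max(m) > 1 + 1e-9)
      msg <- c(msg, "entries must lie in [0, 1]")
    if (max(abs(rowSums(m) - 1)) > 1e-6)
      msg <- c(msg, "every row must sum to 1 (tolerance 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceMap: per-cell-type reference intensity used for evaluation
#'
#' A non-negative observations x cell types matrix against which predicted
#' probability maps are compared: either a one-hot encoding of prior
#' annotations, per-type summed marker-gene expression (max-scaled to
#' \[0, 1\]), or the true mixing proportions of a simulation.
#'
#' @slot values observations x types non-negative matrix.
#' @slot source one of `"annotation_onehot"`, `"marker_gene_sum"`,
#'   `"true_proportions"`.
#' @export
setClass("ReferenceMap",
  representation(values = "matrix", source = "character"))

setValidity("ReferenceMap", function(object) {
  msg <- character()
  if (!object@source %in% c("annotation_onehot", "marker_gene_sum",
                            "true_proportions"))
    msg <- c(msg, "unknown reference map source")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "reference map needs cell-type column names")
  if (length(object@values) && (anyNA(object@values) ||
                                min(object@values) < 0))
    msg <- c(msg, "reference map entries must be non-negative")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: metric values, ranks and Acc Scores for a set of methods
#'
#' @slot values methods x metrics matrix of aggregate metric values.
#' @slot ranks methods x metrics matrix of ranks (best method gets rank M).
#' @slot accScore named per-method Acc Score in (0, 1\].
#' @slot scoreMetrics metrics entering the Acc Score.
#' @export
setClass("EvaluationReport",
  representation(values = "matrix", ranks = "matrix", accScore = "numeric",
                 scoreMetrics = "character"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (!identical(rownames(object@values), names(object@accScore)))
    msg <- c(msg, "accScore names must match the method rows")
  if (length(object@accScore) &&
      (min(object@accScore) <= 0 || max(object@accScore) > 1 + 1e-12))
    msg <- c(msg, "Acc Scores must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic reference/spatial generator
#'
#' Defines a ground-truth simulation with `K` cell types, `G` genes and a
#' disjoint block of `markersPerType` marker genes per type elevated
#' `foldChange`-fold above the negative-binomial baseline
#' (mean `baseMean`, dispersion parameterized so that the NB size is
#' `1/dispersion`). The spatial data set places observations in the unit
#' square; the `"layers"` layout assigns types to `K` horizontal bands.
#' With `cellsPerSpot > 1` each spot pools counts of that many cells drawn
#' from a local type mixture (Gaussian kernel over band centers with
#' standard deviation `1/(4K)` of the square's height), and the true mixing
#' proportions are recorded.
#'
#' @param K number of cell types.
#' @param G number of genes (`K * markersPerType <= G`).
#' @param markersPerType marker genes per type.
#' @param foldChange marker elevation factor (>= 1).
#' @param baseMean baseline negative-binomial mean per gene.
#' @param dispersion NB dispersion; variance is `mu + dispersion * mu^2`.
#' @param nRefPerType reference cells simulated per type.
#' @param nSpatial spatial observations simulated.
#' @param layout `"layers"` (horizontal bands) or `"random"`.
#' @param cellsPerSpot cells pooled per spatial observation (1 = single-cell
#'   resolution with exact labels).
#' @param seed integer seed making both draws reproducible.
#' @return A `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(K = 3, G = 60, markersPerType = 10,
#'                         nRefPerType = 20, nSpatial = 30, seed = 1)
#' @export
simulationConfig <- function(K = 5L, G = 500L, markersPerType = 40L,
                             foldChange = 4, baseMean = 1, dispersion = 0.5,
                             nRefPerType = 200L, nSpatial = 1000L,
                             layout = c("layers", "random"),
                             cellsPerSpot = 1L, seed = 0L) {
  layout <- match.arg(layout)
  out <- new("SimulationConfig", K = as.integer(K), G = as.integer(G),
             markersPerType = as.integer(markersPerType),
             foldChange = as.numeric(foldChange),
             baseMean = as.numeric(baseMean),
             dispersion = as.numeric(dispersion),
             nRefPerType = as.integer(nRefPerType),
             nSpatial = as.integer(nSpatial), layout = layout,
             cellsPerSpot = as.integer(cellsPerSpot),
             seed = as.integer(seed))
  validObject(out)
  out
}

#' @rdname simulationConfig
#' @export
setClass("SimulationConfig",
  representation(K = "integer", G = "integer", markersPerType = "integer",
                 foldChange = "numeric", baseMean = "numeric",
                 dispersion = "numeric", nRefPerType = "integer",
                 nSpatial = "integer", layout = "character",
                 cellsPerSpot = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@K < 1L || object@G < 1L || object@markersPerType < 1L ||
      object@nRefPerType < 1L || object@nSpatial < 1L ||
      object@cellsPerSpot < 1L)
    msg <- c(msg, "all counts must be positive")
  if (object@K * object@markersPerType > object@G)
    msg <- c(msg, "K * markersPerType must not exceed G")
  if (object@foldChange < 1) msg <- c(msg, "foldChange must be >= 1")
  if (object@baseMean <= 0 || object@dispersion <= 0)
    msg <- c(msg, "baseMean and dispersion must be positive")
  if (!object@layout %in% c("layers", "random"))
    msg <- c(msg, "layout must be 'layers' or 'random'")
  if (length(msg)) msg else TRUE
})
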