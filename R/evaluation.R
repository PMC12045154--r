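# Multi-metric evaluation of predicted cell-type maps: per-type cosine,
# Pearson, structural similarity, Kullback-Leibler and Jensen-Shannon
# comparisons against a reference map, combined into a rank-averaged
# accuracy score, plus confusion-matrix and proportion-similarity checks.

#' Similarity / divergence metrics between two per-type maps
#'
#' All metrics compare a predicted vector `p` (one cell type's probability
#' over observations) against a reference vector `r`:
#' * `metricCos` — cosine similarity; 0 if either vector is all-zero.
#' * `metricPPMC` — Pearson product-moment correlation; 0 with a warning
#'   when either vector has zero variance.
#' * `metricSSIM` — global single-window structural similarity. Both
#'   vectors are first max-scaled to \[0, 1\] (dynamic range L = 1,
#'   constants C1 = 0.01^2, C2 = 0.03^2); moments use the population
#'   (1/n) convention.
#' * `metricKL` — Kullback-Leibler divergence KL(r || p) in nats; both
#'   vectors are shifted by `eps` and renormalized to the simplex first.
#' * `metricJS` — Jensen-Shannon divergence in nats, bounded by ln 2.
#'
#' @param p,r equal-length non-negative numeric vectors.
#' @param eps smoothing constant for the divergence metrics (default
#'   1e-12).
#' @return scalar metric value.
#' @export
metricCos <- function(p, r) {
  .checkPair(p, r)
  np <- sqrt(sum(p^2))
  nr <- sqrt(sum(r^2))
  if (np == 0 || nr == 0) return(0)
  sum(p * r) / (np * nr)
}

#' @rdname metricCos
#' @export
metricPPMC <- function(p, r) {
  .checkPair(p, r)
  if (stats::sd(p) == 0 || stats::sd(r) == 0) {
    .warnf("zero-variance vector in Pearson correlation; returning 0")
    return(0)
  }
  stats::cor(p, r)
}

#' @rdname metricCos
#' @export
metricSSIM <- function(p, r) {
  .checkPair(p, r)
  if (max(p) > 0) p <- p / max(p)
  if (max(r) > 0) r <- r / max(r)
  C1 <- 0.01^2
  C2 <- 0.03^2
  n <- length(p)
  mp <- mean(p)
  mr <- mean(r)
  vp <- sum((p - mp)^2) / n
  vr <- sum((r - mr)^2) / n
  cpr <- sum((p - mp) * (r - mr)) / n
  ((2 * mp * mr + C1) * (2 * cpr + C2)) /
    ((mp^2 + mr^2 + C1) * (vp + vr + C2))
}

#' @rdname metricCos
#' @export
metricKL <- function(p, r, eps = 1e-12) {
  .checkPair(p, r)
  q <- .toSimplex(p, eps)
  s <- .toSimplex(r, eps)
  sum(s * log(s / q))
}

#' @rdname metricCos
#' @export
metricJS <- function(p, r, eps = 1e-12) {
  .checkPair(p, r)
  q <- .toSimplex(p, eps)
  s <- .toSimplex(r, eps)
  m <- (q + s) / 2
  sum(q * log(q / m)) / 2 + sum(s * log(s / m)) / 2
}

.checkPair <- function(p, r) {
  if (length(p) != length(r))
    .stopf("vectors differ in length (%d vs %d)", length(p), length(r))
  if (!length(p)) .stopf("empty vectors")
  if (anyNA(p) || anyNA(r)) .stopf("NA values in metric input")
}

.toSimplex <- function(v, eps) {
  v <- v + eps
  v / sum(v)
}

#' Build a reference map for evaluation
#'
#' Marker mode: column k holds each observation's summed normalized
#' expression of type k's marker genes, max-scaled to \[0, 1\]
#' (conventionally the top 20 type-specific markers). Annotation mode:
#' a one-hot encoding of prior labels.
#'
#' @param spatial normalized [ExpressionDataset] (marker mode).
#' @param markers named list (one entry per cell type) of marker gene
#'   vectors; each is truncated to `nTop` genes.
#' @param labels per-observation annotations (annotation mode); used when
#'   `markers` is `NULL`. Defaults to the labels carried by `spatial`.
#' @param vocabulary optional type order for annotation mode (default:
#'   first appearance).
#' @param nTop markers used per type (default 20).
#' @return A [ReferenceMap].
#' @export
buildReferenceMap <- function(spatial, markers = NULL, labels = NULL,
                              vocabulary = NULL, nTop = 20) {
  stopifnot(is(spatial, "ExpressionDataset"))
  if (!is.null(markers)) {
    if (layerTag(spatial) != "normalized")
      .stopf("marker-mode reference maps need normalized expression")
    if (is.null(names(markers)))
      .stopf("'markers' must be a named list (one entry per cell type)")
    X <- .denseMatrix(exprValues(spatial))
    cols <- lapply(names(markers), function(ct) {
      g <- intersect(utils::head(markers[[ct]], nTop), rownames(X))
      if (!length(g)) .stopf("no markers available for type '%s'", ct)
      v <- colSums(X[g, , drop = FALSE])
      if (max(v) > 0) v / max(v) else v
    })
    m <- do.call(cbind, cols)
    dimnames(m) <- list(obsIds(spatial), names(markers))
    src <- "marker_gene_sum"
  } else {
    if (is.null(labels)) labels <- cellLabels(spatial)
    if (is.null(labels)) .stopf("no labels available for annotation mode")
    labels <- as.character(labels)
    if (is.null(vocabulary)) vocabulary <- unique(labels)
    if (!all(labels %in% vocabulary))
      .stopf("labels outside the given vocabulary")
    m <- matrix(0, length(labels), length(vocabulary),
                dimnames = list(obsIds(spatial), vocabulary))
    m[cbind(seq_along(labels), match(labels, vocabulary))] <- 1
    src <- "annotation_onehot"
  }
  new("ReferenceMap", values = m, source = src)
}

#' Aggregate the metric panel over cell types
#'
#' Computes every metric per cell-type column of the prediction against
#' the matching reference column and averages over types (unweighted).
#'
#' @param pm a [CellTypeProbabilityMatrix] (or plain matrix).
#' @param ref a [ReferenceMap] (or plain matrix) with the same types.
#' @return named numeric: `COS`, `PPMC`, `SSIM`, `KL`, `JS`.
#' @export
aggregateMetrics <- function(pm, ref) {
  P <- if (is(pm, "CellTypeProbabilityMatrix")) probValues(pm)
       else as.matrix(pm)
  R <- if (is(ref, "ReferenceMap")) mapValues(ref) else as.matrix(ref)
  if (!identical(dim(P), dim(R)))
    .stopf("prediction (%d x %d) and reference (%d x %d) shapes differ",
           nrow(P), ncol(P), nrow(R), ncol(R))
  if (!is.null(colnames(P)) && !is.null(colnames(R)) &&
      !identical(colnames(P), colnames(R)))
    .stopf("cell-type vocabularies differ between prediction and reference")
  perType <- vapply(seq_len(ncol(P)), function(k) {
    p <- P[, k]
    r <- R[, k]
    c(COS = metricCos(p, r), PPMC = metricPPMC(p, r),
      SSIM = metricSSIM(p, r), KL = metricKL(p, r), JS = metricJS(p, r))
  }, numeric(5L))
  rowMeans(perType)
}

#' Rank-averaged accuracy score (Acc Score)
#'
#' For each metric the methods are ranked so that the best method receives
#' rank M (higher is better for COS/PPMC/SSIM, lower is better for KL/JS),
#' ties receiving the average rank. The Acc Score of a method is its mean
#' rank over the scored metrics divided by M, so it lies in (0, 1\] and the
#' best possible score is 1.
#'
#' @param values methods x metrics matrix (rownames = methods).
#' @param metrics metrics entering the score; default the four named
#'   panel metrics `COS`, `PPMC`, `SSIM`, `KL` (JS may be added).
#' @return list with `score` (named per-method), `ranks`
#'   (methods x metrics over all available metrics).
#' @export
accScore <- function(values, metrics = c("COS", "PPMC", "SSIM", "KL")) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) .stopf("Acc Score needs >= 2 methods")
  if (is.null(rownames(values))) .stopf("'values' needs method rownames")
  missing <- setdiff(metrics, colnames(values))
  if (length(missing))
    .stopf("metric value(s) missing: %s", paste(missing, collapse = ", "))
  if (anyNA(values[, metrics])) .stopf("NA metric values")
  lowerBetter <- c("KL", "JS")
  ranks <- vapply(colnames(values), function(mt) {
    v <- values[, mt]
    if (mt %in% lowerBetter) rank(-v, ties.method = "average")
    else rank(v, ties.method = "average")
  }, numeric(nrow(values)))
  rownames(ranks) <- rownames(values)
  M <- nrow(values)
  score <- rowMeans(ranks[, metrics, drop = FALSE]) / M
  list(score = score, ranks = ranks)
}

#' Confusion matrix between predicted and annotated labels
#'
#' Entry (i, j) is the fraction of observations annotated as type i that
#' were predicted as type j; rows of non-empty classes sum to 1. The
#' vocabulary is the union of both label sets (annotation order first).
#'
#' @param predicted,annotated equal-length character vectors.
#' @return list with `matrix` (row-normalized K x K) and `accuracy`
#'   (overall fraction of agreeing observations).
#' @export
confusionMatrix <- function(predicted, annotated) {
  predicted <- as.character(predicted)
  annotated <- as.character(annotated)
  if (length(predicted) != length(annotated))
    .stopf("label vectors differ in length (%d vs %d)",
           length(predicted), length(annotated))
  vocab <- union(unique(annotated), unique(predicted))
  counts <- table(factor(annotated, levels = vocab),
                  factor(predicted, levels = vocab))
  m <- matrix(as.numeric(counts), nrow = length(vocab),
              dimnames = list(annotated = vocab, predicted = vocab))
  tot <- rowSums(m)
  nz <- tot > 0
  m[nz, ] <- m[nz, , drop = FALSE] / tot[nz]
  list(matrix = m, accuracy = mean(predicted == annotated))
}

#' Similarity of predicted and reference cell-type proportions
#'
#' The predicted proportion of a type is the mean of its probability
#' column (`mode = "mean"`) or its hard-label frequency
#' (`mode = "hard"`); the vector is compared to the reference proportions
#' by Pearson correlation and cosine similarity.
#'
#' @param pm a [CellTypeProbabilityMatrix].
#' @param referenceProportions named (or vocabulary-ordered) non-negative
#'   vector of reference proportions.
#' @param mode `"mean"` (default) or `"hard"`.
#' @return named numeric `c(PPMC = , COS = )`.
#' @export
proportionSimilarity <- function(pm, referenceProportions,
                                 mode = c("mean", "hard")) {
  stopifnot(is(pm, "CellTypeProbabilityMatrix"))
  mode <- match.arg(mode)
  vocab <- typeVocabulary(pm)
  if (!is.null(names(referenceProportions))) {
    if (!setequal(names(referenceProportions), vocab))
      .stopf("reference proportions do not cover the prediction vocabulary")
    referenceProportions <- referenceProportions[vocab]
  } else if (length(referenceProportions) != length(vocab)) {
    .stopf("reference proportions length (%d) does not match vocabulary (%d)",
           length(referenceProportions), length(vocab))
  }
  pred <- if (mode == "mean") colMeans(probValues(pm))
    else as.numeric(table(factor(hardLabels(pm), levels = vocab))) /
      nrow(probValues(pm))
  c(PPMC = metricPPMC(pred, as.numeric(referenceProportions)),
    COS = metricCos(pred, as.numeric(referenceProportions)))
}

#' Benchmark several methods against one reference map
#'
#' Computes the aggregate metric panel per method and the rank-averaged
#' Acc Score.
#'
#' @param predictions named list (>= 2) of [CellTypeProbabilityMatrix]
#'   objects sharing observations and vocabulary.
#' @param reference a [ReferenceMap].
#' @param scoreMetrics metrics entering the Acc Score (default COS, PPMC,
#'   SSIM, KL; JS is always reported).
#' @return An [EvaluationReport].
#' @export
runBenchmark <- function(predictions, reference,
                         scoreMetrics = c("COS", "PPMC", "SSIM", "KL")) {
  if (!is.list(predictions) || length(predictions) < 2L)
    .stopf("benchmarking needs >= 2 methods")
  if (is.null(names(predictions)) || any(!nzchar(names(predictions))))
    .stopf("'predictions' must be a named list")
  vocab <- typeVocabulary(reference)
  vals <- t(vapply(predictions, function(pm) {
    if (!identical(typeVocabulary(pm), vocab))
      .stopf("vocabulary mismatch between a prediction and the reference")
    aggregateMetrics(pm, reference)
  }, numeric(5L)))
  sc <- accScore(vals, metrics = scoreMetrics)
  out <- new("EvaluationReport", values = vals, ranks = sc$ranks,
             accScore = sc$score, scoreMetrics = scoreMetrics)
  validObject(out)
  out
}

#' Write an evaluation report as TSV
#'
#' One row per method: metric values, ranks and the Acc Score.
#'
#' @param report an [EvaluationReport].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  vals <- metricValues(report)
  ranks <- metricRanks(report)
  colnames(ranks) <- paste0("rank_", colnames(ranks))
  df <- data.frame(method = rownames(vals), vals, ranks,
                   acc_score = accScores(report), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
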