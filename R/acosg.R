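# ACOSG: penalized-cosine (COSG-style) marker scoring fused with a
# supervised per-gene attention importance.

#' Cosine similarity between genes and cell-type indicators
#'
#' For gene g and cell type k, `lambda[g, k]` is the cosine of the angle
#' between the gene's expression vector over all cells and the 0/1
#' indicator vector of type k. All-zero genes get lambda 0 by convention.
#'
#' @param ds normalized [ExpressionDataset].
#' @param labels per-cell labels; default taken from `ds`. Either a
#'   character vector or a list as returned by [encodeLabels()].
#' @return genes x types matrix of cosine similarities in \[-1, 1\],
#'   columns named by the label vocabulary.
#' @export
cosineLambda <- function(ds, labels = NULL) {
  stopifnot(is(ds, "ExpressionDataset"))
  if (layerTag(ds) != "normalized")
    .stopf("cosineLambda expects a normalized data set")
  enc <- .resolveLabels(ds, labels)
  X <- .denseMatrix(exprValues(ds))             # genes x cells
  K <- length(enc$vocabulary)
  U <- matrix(0, ncol(X), K)
  U[cbind(seq_len(ncol(X)), enc$codes + 1L)] <- 1
  num <- X %*% U                                 # genes x K
  geneNorm <- sqrt(rowSums(X^2))
  typeNorm <- sqrt(colSums(U))
  lambda <- num / outer(geneNorm, typeNorm)
  lambda[geneNorm == 0, ] <- 0
  lambda <- pmin(pmax(lambda, -1), 1)
  dimnames(lambda) <- list(rownames(X), enc$vocabulary)
  lambda
}

.resolveLabels <- function(ds, labels) {
  if (is.null(labels)) return(encodeLabels(ds))
  if (is.list(labels)) {
    stopifnot(all(c("vocabulary", "codes") %in% names(labels)))
    if (length(labels$codes) != ncol(ds))
      .stopf("label codes length (%d) does not match observations (%d)",
             length(labels$codes), ncol(ds))
    if (any(labels$codes < 0L) ||
        any(labels$codes >= length(labels$vocabulary)))
      .stopf("label codes outside [0, K)")
    return(labels)
  }
  if (length(labels) != ncol(ds))
    .stopf("labels length (%d) does not match observations (%d)",
           length(labels), ncol(ds))
  encodeLabels(as.character(labels))
}

#' Penalized cosine (COSG) score
#'
#' `score[g, k] = sign(lambda) * lambda^2 / (lambda^2 + mu * sum_{i != k}
#' lambda[g, i]^2)`, 0 when the denominator vanishes. `mu` trades
#' specificity against expression: `mu = 0` reduces the score to the sign
#' of lambda (pure cosine ranking), larger `mu` penalizes genes that also
#' point towards other types.
#'
#' @param lambda genes x types cosine matrix from [cosineLambda()].
#' @param mu penalty (>= 0), default 1.
#' @return genes x types matrix of scores in \[-1, 1\].
#' @export
cosgScore <- function(lambda, mu = 1) {
  if (!is.matrix(lambda)) .stopf("'lambda' must be a matrix")
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    .stopf("'mu' must be a single number >= 0")
  l2 <- lambda^2
  other <- rowSums(l2) - l2                      # sum over i != k
  denom <- l2 + mu * other
  score <- ifelse(denom == 0, 0, sign(lambda) * l2 / denom)
  dimnames(score) <- dimnames(lambda)
  score
}

#' Supervised per-gene attention weights
#'
#' Trains a small classifier on the labelled reference in which every gene
#' passes through a learned multiplicative gate (a per-gene scalar through
#' softplus) before a 64-unit ReLU hidden layer and a softmax output. The
#' attention weight of a gene is the softmax-normalized activation of its
#' learned gate (`softplus` of the gate parameter), so the weights are
#' non-negative and sum to one. Expression is standardized per gene
#' beforehand, so the weights reflect what the gate learned rather than
#' raw expression magnitude or distribution shape.
#'
#' Gene-indexed parameters are initialized in canonical (sorted gene name)
#' order, making the result equivariant under permutation of the input
#' genes at a fixed seed.
#'
#' @param ds normalized [ExpressionDataset] (>= 2 cell types).
#' @param labels as in [cosineLambda()].
#' @param epochs training epochs (default 30).
#' @param learningRate Adagrad learning rate (default 0.01).
#' @param hiddenUnits hidden layer width (default 64).
#' @param batchSize mini-batch size (default 128).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return named per-gene attention weights summing to 1.
#' @export
trainAttention <- function(ds, labels = NULL, epochs = 30,
                           learningRate = 0.01, hiddenUnits = 64,
                           batchSize = 128, seed = 0) {
  stopifnot(is(ds, "ExpressionDataset"))
  if (layerTag(ds) != "normalized")
    .stopf("trainAttention expects a normalized data set")
  enc <- .resolveLabels(ds, labels)
  K <- length(enc$vocabulary)
  if (K < 2L) .stopf("attention requires >=2 classes")
  X <- t(.denseMatrix(exprValues(ds)))           # cells x genes
  genes <- colnames(X)
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2L, stats::sd), 1e-8)
  X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  n <- nrow(X)
  G <- ncol(X)
  y <- enc$codes + 1L

  .withSeed(seed, {
    # init tied to gene identity: draw first-layer columns in sorted-name
    # order, then map onto the actual column order
    ord <- order(genes)
    W1canon <- matrix(stats::rnorm(hiddenUnits * G, sd = sqrt(2 / G)),
                      hiddenUnits, G)
    W1 <- matrix(0, hiddenUnits, G)
    W1[, ord] <- W1canon
    b1 <- numeric(hiddenUnits)
    W2 <- matrix(stats::rnorm(K * hiddenUnits, sd = sqrt(2 / hiddenUnits)),
                 K, hiddenUnits)
    b2 <- numeric(K)
    gate <- rep(.softplusInverse(1), G)

    acc <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0,
                gate = gate * 0)
    lr <- learningRate
    epsA <- 1e-8
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = batchSize)
      for (s in starts) {
        b <- idx[s:min(s + batchSize - 1L, n)]
        Xb <- X[b, , drop = FALSE]
        B <- length(b)
        gAct <- .softplus(gate)
        A <- sweep(Xb, 2L, gAct, "*")
        Z1 <- A %*% t(W1) + matrix(b1, B, hiddenUnits, byrow = TRUE)
        H <- .relu(Z1)
        Z2 <- H %*% t(W2) + matrix(b2, B, K, byrow = TRUE)
        P <- .softmaxRows(Z2)
        Y <- matrix(0, B, K)
        Y[cbind(seq_len(B), y[b])] <- 1
        dZ2 <- (P - Y) / B
        gW2 <- t(dZ2) %*% H
        gb2 <- colSums(dZ2)
        dH <- dZ2 %*% W2
        dH[Z1 <= 0] <- 0
        gW1 <- t(dH) %*% A
        gb1 <- colSums(dH)
        dA <- dH %*% W1
        gGate <- colSums(dA * Xb) * .sigmoid(gate)
        acc$W1 <- acc$W1 + gW1^2; acc$b1 <- acc$b1 + gb1^2
        acc$W2 <- acc$W2 + gW2^2; acc$b2 <- acc$b2 + gb2^2
        acc$gate <- acc$gate + gGate^2
        W1 <- W1 - lr * gW1 / (sqrt(acc$W1) + epsA)
        b1 <- b1 - lr * gb1 / (sqrt(acc$b1) + epsA)
        W2 <- W2 - lr * gW2 / (sqrt(acc$W2) + epsA)
        b2 <- b2 - lr * gb2 / (sqrt(acc$b2) + epsA)
        gate <- gate - lr * gGate / (sqrt(acc$gate) + epsA)
      }
    }
    stats::setNames(.softmaxVec(.softplus(gate)), genes)
  })
}

#' Fuse COSG scores with attention weights and select a gene panel
#'
#' `fused[g, k] = cosg[g, k] * attention[g] / max(attention)`. With
#' `perType = TRUE` the top `nTop` genes of every cell type by fused score
#' are unioned; otherwise the top `nTop` genes by the max-over-types fused
#' score are taken. Ties break by lexicographic gene name. The returned
#' panel follows the reference gene order (the row order of `cosg`).
#'
#' @param cosg genes x types score matrix from [cosgScore()].
#' @param attention per-gene weights from [trainAttention()] (any
#'   non-negative vector; uniform weights reduce the selection to pure
#'   COSG ranking).
#' @param nTop genes per type (or globally); clamped with a warning when
#'   it exceeds the gene count.
#' @param perType select per cell type (default) or globally.
#' @return list with `panel` (ordered gene names) and `fused` (the fused
#'   score matrix).
#' @export
fuseAndSelect <- function(cosg, attention, nTop = 50, perType = TRUE) {
  if (!is.matrix(cosg)) .stopf("'cosg' must be a matrix")
  genes <- rownames(cosg)
  if (is.null(genes)) .stopf("'cosg' must carry gene rownames")
  if (length(attention) != nrow(cosg))
    .stopf("attention length (%d) does not match gene count (%d)",
           length(attention), nrow(cosg))
  if (!is.null(names(attention))) attention <- attention[genes]
  if (anyNA(attention) || any(attention < 0))
    .stopf("attention weights must be non-negative and cover every gene")
  if (nTop < 1L) .stopf("'nTop' must be >= 1")
  if (nTop > nrow(cosg)) {
    .warnf("nTop (%d) exceeds gene count (%d); using all genes",
           nTop, nrow(cosg))
    nTop <- nrow(cosg)
  }
  amax <- max(attention)
  rel <- if (amax > 0) attention / amax else rep(1, length(attention))
  fused <- cosg * rel
  dimnames(fused) <- dimnames(cosg)
  topOf <- function(score) {
    genes[order(-score, genes)[seq_len(nTop)]]
  }
  selected <- if (perType) {
    unique(unlist(lapply(seq_len(ncol(fused)),
                         function(k) topOf(fused[, k]))))
  } else {
    topOf(apply(fused, 1L, max))
  }
  list(panel = genes[genes %in% selected], fused = fused)
}

#' Rank marker genes with ACOSG and build a GeneScoreTable
#'
#' Convenience wrapper running [cosineLambda()], [cosgScore()],
#' [trainAttention()] and [fuseAndSelect()] on a labelled, normalized
#' reference.
#'
#' @param ds normalized, labelled [ExpressionDataset].
#' @param labels optional labels (default from `ds`).
#' @param mu COSG penalty (default 1).
#' @param nTop panel size per type (default 50).
#' @param perType per-type selection (default TRUE).
#' @param attention optional precomputed per-gene weights; when `NULL`
#'   they are trained via [trainAttention()].
#' @param attentionControl list of arguments passed to [trainAttention()]
#'   (`epochs`, `learningRate`, `hiddenUnits`, `batchSize`, `seed`).
#' @return A [GeneScoreTable].
#' @export
selectFeatureGenes <- function(ds, labels = NULL, mu = 1, nTop = 50,
                               perType = TRUE, attention = NULL,
                               attentionControl = list()) {
  enc <- .resolveLabels(ds, labels)
  lambda <- cosineLambda(ds, enc)
  cosg <- cosgScore(lambda, mu = mu)
  if (is.null(attention))
    attention <- do.call(trainAttention,
                         c(list(ds = ds, labels = enc), attentionControl))
  else if (!is.null(names(attention)))
    attention <- attention[rownames(lambda)]
  attention <- attention / sum(attention)
  sel <- fuseAndSelect(cosg, attention, nTop = nTop, perType = perType)
  out <- new("GeneScoreTable", lambda = lambda, cosg = cosg,
             attention = stats::setNames(as.numeric(attention),
                                         rownames(lambda)),
             fused = sel$fused, mu = as.numeric(mu),
             nTop = as.integer(min(nTop, nrow(lambda))),
             perType = isTRUE(perType), panel = sel$panel)
  validObject(out)
  out
}

#' Export gene scores / panels
#'
#' `writeGeneScoreTable` writes the long-format scores as TSV;
#' `writeGenePanel` writes one gene per line (order significant, consumed
#' verbatim by the classifier); `readGenePanel` reads it back.
#'
#' @param x a [GeneScoreTable].
#' @param path output path.
#' @return the path, invisibly (`readGenePanel`: character vector).
#' @export
writeGeneScoreTable <- function(x, path) {
  stopifnot(is(x, "GeneScoreTable"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneScoreTable
#' @export
writeGenePanel <- function(x, path) {
  panel <- if (is(x, "GeneScoreTable")) genePanel(x) else as.character(x)
  writeLines(panel, path)
  invisible(path)
}

#' @rdname writeGeneScoreTable
#' @export
readGenePanel <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  readLines(path)
}
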