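# Small in-code fixtures shared across test files.

# Dense genes x observations count matrix with names.
toyCounts <- function(G = 4, n = 6, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(G * n, lambda), G, n,
              dimnames = list(sprintf("g%02d", seq_len(G)),
                              sprintf("c%02d", seq_len(n))))
  m
}

# Normalized dataset directly from arbitrary non-negative values.
normalizedDataset <- function(values, labels = NULL, coords = NULL) {
  ExpressionDataset(values, labels = labels, coords = coords,
                    layerTag = "normalized")
}

# Random labelled normalized dataset: G genes, n cells, K types.
randomLabelledDataset <- function(G = 20, n = 30, K = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(G * n), G, n,
              dimnames = list(sprintf("g%02d", seq_len(G)),
                              sprintf("c%02d", seq_len(n))))
  labels <- sample(paste0("T", seq_len(K)), n, replace = TRUE)
  # guarantee every type occurs
  labels[seq_len(K)] <- paste0("T", seq_len(K))
  normalizedDataset(m, labels = labels)
}

# Two-type expression data in which exactly one gene separates the
# classes; everything else is NB noise with identical distribution.
oneMarkerDataset <- function(G = 50, nPerType = 200, fold = 8, seed = 0) {
  set.seed(seed)
  n <- 2L * nPerType
  m <- matrix(rnbinom(G * n, mu = 1, size = 2), G, n)
  labels <- rep(c("A", "B"), each = nPerType)
  bIdx <- which(labels == "B")
  m[1L, bIdx] <- rnbinom(length(bIdx), mu = fold, size = 2)
  dimnames(m) <- list(sprintf("g%03d", seq_len(G)),
                      sprintf("c%04d", seq_len(n)))
  ExpressionDataset(m, labels = labels, layerTag = "raw")
}

# Probability matrix helper.
toyProbMatrix <- function(m, ids = NULL, types = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- if (is.null(ids)) paste0("o", seq_len(nrow(m))) else ids
  if (is.null(colnames(m)))
    colnames(m) <- if (is.null(types)) paste0("t", seq_len(ncol(m)))
                   else types
  CellTypeProbabilityMatrix(m)
}
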