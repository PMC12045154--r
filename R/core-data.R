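# Readers/writers and shared preprocessing for reference and spatial data.

#' Read an expression data set from disk
#'
#' Supported containers:
#' * `"csv"` — dense observations x genes table with gene names in the
#'   header. A leading column headed `obs_id`, `cell_id`, `barcode`, `id`
#'   or left blank supplies observation ids; otherwise ids `obs1..obsN`
#'   are generated.
#' * `"mtx"` — a directory with `matrix.mtx` (genes x observations
#'   Matrix-Market triplets), `genes.tsv` and `barcodes.tsv`, the 10x
#'   convention. Optional `labels.tsv` (one cell type per barcode) and
#'   `coords.tsv` (x,y per barcode) are attached when present.
#' * `"h5ad"` — AnnData HDF5 (requires the rhdf5 package): dense or
#'   CSR/CSC `X`, `var`/`obs` `_index`, an optional categorical or string
#'   obs column named by `labelCol`, and optional `obsm/spatial`
#'   coordinates.
#'
#' Duplicated gene names are resolved by keeping the first occurrence,
#' with a warning.
#'
#' @param path file (csv, h5ad) or directory (mtx).
#' @param format one of `"auto"`, `"csv"`, `"mtx"`, `"h5ad"`; `"auto"`
#'   infers from the path.
#' @param labelCol for h5ad: obs column holding cell-type labels
#'   (attached when present).
#' @return An [ExpressionDataset] with `layerTag = "raw"`.
#' @export
readExpressionDataset <- function(path, format = c("auto", "csv", "mtx",
                                                   "h5ad"),
                                  labelCol = "cell_type") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
      else if (grepl("\\.h5ad$", path, ignore.case = TRUE)) "h5ad"
      else "csv"
  }
  if (format == "mtx") {
    if (!dir.exists(path)) .stopf("directory not found: %s", path)
  } else if (!file.exists(path)) {
    .stopf("file not found: %s", path)
  }
  switch(format,
         csv = .readCSVDataset(path),
         mtx = .readMtxDataset(path),
         h5ad = .readH5adDataset(path, labelCol))
}

.dedupGenes <- function(m) {
  gn <- rownames(m)
  dup <- duplicated(gn)
  if (any(dup)) {
    .warnf("dropping %d duplicated gene name(s), keeping first occurrence: %s",
           sum(dup), paste(unique(gn[dup]), collapse = ", "))
    m <- m[!dup, , drop = FALSE]
  }
  m
}

.readCSVDataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(df)) .stopf("empty table: %s", path)
  # a leading id column is recognized by its header; every other column
  # is an expression column named by its gene
  idHeaders <- c("", "obs_id", "cell_id", "barcode", "id", "X")
  if (colnames(df)[1L] %in% idHeaders) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  } else {
    ids <- paste0("obs", seq_len(nrow(df)))
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      .stopf("non-numeric entry at row %d, column '%s' of %s",
             bad, colnames(df)[j], path)
    }
  }
  m <- t(as.matrix(df))          # genes x observations
  colnames(m) <- ids
  m <- .dedupGenes(m)
  .asRawDataset(m)
}

.readMtxDataset <- function(dir) {
  fm <- file.path(dir, "matrix.mtx")
  fg <- file.path(dir, "genes.tsv")
  fb <- file.path(dir, "barcodes.tsv")
  for (f in c(fm, fg, fb))
    if (!file.exists(f)) .stopf("file not found: %s", f)
  m <- Matrix::readMM(fm)
  genes <- utils::read.delim(fg, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  barcodes <- utils::read.delim(fb, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m))
    .stopf("gene list length (%d) does not match matrix rows (%d)",
           length(genes), nrow(m))
  if (length(barcodes) != ncol(m))
    .stopf("barcode list length (%d) does not match matrix columns (%d)",
           length(barcodes), ncol(m))
  m <- as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, barcodes)
  m <- .dedupGenes(m)
  labels <- coords <- NULL
  fl <- file.path(dir, "labels.tsv")
  if (file.exists(fl)) {
    labels <- utils::read.delim(fl, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
    if (length(labels) != ncol(m))
      .stopf("labels.tsv length (%d) does not match barcodes (%d)",
             length(labels), ncol(m))
  }
  fc <- file.path(dir, "coords.tsv")
  if (file.exists(fc)) {
    coords <- as.matrix(utils::read.delim(fc, header = FALSE))
    if (nrow(coords) != ncol(m) || ncol(coords) != 2L)
      .stopf("coords.tsv must hold two columns, one row per barcode")
  }
  .asRawDataset(m, labels = labels, coords = coords)
}

#' Write an expression data set to disk
#'
#' @param ds an [ExpressionDataset].
#' @param path output directory (`"mtx"`) or file (`"csv"`).
#' @param format `"mtx"` (matrix.mtx + genes.tsv + barcodes.tsv, plus
#'   labels.tsv / coords.tsv when present), `"csv"` (dense observations x
#'   genes with an `obs_id` first column) or `"h5ad"` (minimal AnnData,
#'   requires rhdf5).
#' @return `path`, invisibly.
#' @export
writeExpressionDataset <- function(ds, path, format = c("mtx", "csv",
                                                        "h5ad")) {
  format <- match.arg(format)
  stopifnot(is(ds, "ExpressionDataset"))
  if (format == "h5ad") {
    return(.writeH5adDataset(ds, path))
  } else if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- exprValues(ds)
    Matrix::writeMM(as(as(m, "dMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(geneNames(ds), file.path(path, "genes.tsv"))
    writeLines(obsIds(ds), file.path(path, "barcodes.tsv"))
    if (!is.null(cellLabels(ds)))
      writeLines(cellLabels(ds), file.path(path, "labels.tsv"))
    xy <- spatialCoords(ds)
    if (!is.null(xy))
      utils::write.table(xy, file.path(path, "coords.tsv"), sep = "\t",
                         row.names = FALSE, col.names = FALSE)
  } else {
    m <- t(.denseMatrix(exprValues(ds)))     # observations x genes
    df <- data.frame(obs_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Restrict two data sets to their shared genes
#'
#' Keeps only genes co-expressed (present) in both the reference and the
#' spatial data set, in the reference's gene order; observations are
#' untouched.
#'
#' @param reference,spatial [ExpressionDataset] objects.
#' @return list with elements `reference` and `spatial`.
#' @export
intersectGenes <- function(reference, spatial) {
  stopifnot(is(reference, "ExpressionDataset"),
            is(spatial, "ExpressionDataset"))
  shared <- intersect(geneNames(reference), geneNames(spatial))
  if (!length(shared)) .stopf("no shared genes between the two data sets")
  list(reference = reference[shared, ], spatial = spatial[shared, ])
}

#' Library-size normalization with optional log transform
#'
#' Scales every observation's counts to sum to `targetSum`, then (by
#' default) applies `log1p`. All-zero observations are left at zero and
#' counted in a warning. Train and test data must share one scheme; the
#' pipeline applies this identically to reference and spatial data.
#'
#' @param ds raw [ExpressionDataset].
#' @param targetSum per-observation total after scaling (default 1e4).
#' @param logTransform apply natural `log1p` after scaling.
#' @return normalized [ExpressionDataset] (`layerTag = "normalized"`).
#' @export
normalizeDataset <- function(ds, targetSum = 1e4, logTransform = TRUE) {
  stopifnot(is(ds, "ExpressionDataset"))
  if (layerTag(ds) != "raw")
    .stopf("normalizeDataset expects raw counts (layerTag 'raw')")
  if (!is.numeric(targetSum) || length(targetSum) != 1L || targetSum <= 0)
    .stopf("'targetSum' must be a positive number")
  m <- exprValues(ds)
  tot <- Matrix::colSums(m)
  zero <- tot == 0
  if (any(zero))
    .warnf("%d all-zero observation(s) left unscaled", sum(zero))
  sc <- ifelse(zero, 0, targetSum / tot)
  if (is(m, "sparseMatrix")) {
    m2 <- m %*% Matrix::Diagonal(x = sc)
    dimnames(m2) <- dimnames(m)
  } else {
    m2 <- sweep(m, 2L, sc, "*")
  }
  if (logTransform) m2 <- log1p(m2)
  ExpressionDataset(m2, labels = cellLabels(ds), coords = spatialCoords(ds),
                    layerTag = "normalized")
}

#' Encode cell-type labels as 0-based integers
#'
#' The vocabulary is ordered by first appearance in the data set.
#'
#' @param ds labelled [ExpressionDataset] (or a character vector of labels).
#' @return list with `vocabulary` (ordered unique cell types) and `codes`
#'   (integer vector in `[0, K)`).
#' @export
encodeLabels <- function(ds) {
  labels <- if (is(ds, "ExpressionDataset")) cellLabels(ds)
            else as.character(ds)
  if (is.null(labels)) .stopf("data set carries no cell-type labels")
  if (anyNA(labels) || any(!nzchar(labels)))
    .stopf("labels must be non-empty strings")
  vocabulary <- unique(labels)
  list(vocabulary = vocabulary,
       codes = match(labels, vocabulary) - 1L)
}

#' Write / read a cell-type probability matrix as CSV
#'
#' The CSV holds `obs_id` as first column and one column per cell type in
#' vocabulary order; the round trip is lossless to well below 1e-9.
#'
#' @param pm a [CellTypeProbabilityMatrix].
#' @param path CSV path.
#' @return `writeProbabilityMatrix`: `path` invisibly;
#'   `readProbabilityMatrix`: the matrix read back.
#' @export
writeProbabilityMatrix <- function(pm, path) {
  stopifnot(is(pm, "CellTypeProbabilityMatrix"))
  m <- probValues(pm)
  df <- data.frame(obs_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stopf("cannot write probability matrix to %s", path)
  invisible(path)
}

#' @rdname writeProbabilityMatrix
#' @export
readProbabilityMatrix <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  CellTypeProbabilityMatrix(m)
}
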