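# Minimal AnnData (h5ad) interchange built on rhdf5. Covers the subset of
# the format the pipeline needs: dense or CSR/CSC X, obs/var indices, one
# categorical-or-string obs column for labels, obsm/spatial coordinates.

.requireRhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    .stopf("h5ad support requires the 'rhdf5' package")
}

.h5Index <- function(path, group) {
  at <- tryCatch(rhdf5::h5readAttributes(path, group),
                 error = function(e) list())
  idx <- if (!is.null(at[["_index"]])) as.character(at[["_index"]])
         else "_index"
  as.character(rhdf5::h5read(path, paste0(group, "/", idx)))
}

.readH5adDataset <- function(path, labelCol = "cell_type") {
  .requireRhdf5()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  obsNames <- .h5Index(path, "obs")
  varNames <- .h5Index(path, "var")
  xEntry <- contents[contents$group == "/" & contents$name == "X", ]
  if (!nrow(xEntry)) .stopf("no X matrix in %s", path)
  if (xEntry$otype[1L] == "H5I_DATASET") {
    # anndata stores X as (n_obs, n_var); rhdf5 reverses the axes, so the
    # matrix arrives genes x observations, which is our internal layout.
    m <- rhdf5::h5read(path, "X")
    storage.mode(m) <- "double"
  } else {
    at <- rhdf5::h5readAttributes(path, "X")
    dataV <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    shape <- as.integer(at$shape)            # (n_obs, n_var)
    enc <- as.character(at[["encoding-type"]])
    if (length(enc) && grepl("csc", enc)) {
      m <- Matrix::t(methods::new("dgCMatrix", p = indptr, i = indices,
                                  x = dataV, Dim = shape))
    } else {                                 # CSR over obs == CSC of t(X)
      m <- methods::new("dgCMatrix", p = indptr, i = indices, x = dataV,
                        Dim = c(shape[2L], shape[1L]))
    }
  }
  if (nrow(m) != length(varNames) || ncol(m) != length(obsNames))
    .stopf("X dimensions (%d x %d) do not match var/obs lengths (%d, %d)",
           nrow(m), ncol(m), length(varNames), length(obsNames))
  dimnames(m) <- list(varNames, obsNames)
  m <- .dedupGenes(m)
  labels <- .readH5adObsColumn(path, contents, labelCol)
  coords <- NULL
  if (any(contents$group == "/obsm" & contents$name == "spatial")) {
    xy <- rhdf5::h5read(path, "obsm/spatial")  # arrives 2 x n_obs
    coords <- t(matrix(as.numeric(xy), nrow = 2L))
  }
  .asRawDataset(m, labels, coords)
}

.readH5adObsColumn <- function(path, contents, column) {
  inObs <- contents[contents$group == "/obs" & contents$name == column, ]
  if (!nrow(inObs)) return(NULL)
  if (inObs$otype[1L] == "H5I_GROUP") {         # categorical encoding
    categories <- as.character(
      rhdf5::h5read(path, sprintf("obs/%s/categories", column)))
    codes <- as.integer(
      rhdf5::h5read(path, sprintf("obs/%s/codes", column)))
    ifelse(codes < 0L, NA_character_, categories[codes + 1L])
  } else {
    as.character(rhdf5::h5read(path, paste0("obs/", column)))
  }
}

# Tag integer matrices raw; anything else is treated as already normalized.
.asRawDataset <- function(m, labels = NULL, coords = NULL) {
  vals <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  tag <- if (!length(vals) || .isWholeNumber(vals)) "raw" else "normalized"
  if (tag == "normalized")
    .warnf("matrix holds non-integer values; tagging as 'normalized'")
  ExpressionDataset(m, labels = labels, coords = coords, layerTag = tag)
}

.writeH5adDataset <- function(ds, path) {
  .requireRhdf5()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  # genes x obs in R becomes (n_obs, n_var) in the file, matching anndata.
  rhdf5::h5write(.denseMatrix(exprValues(ds)), path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(obsIds(ds), path, "obs/_index")
  rhdf5::h5write(geneNames(ds), path, "var/_index")
  if (!is.null(cellLabels(ds)))
    rhdf5::h5write(cellLabels(ds), path, "obs/cell_type")
  xy <- spatialCoords(ds)
  if (!is.null(xy)) {
    rhdf5::h5createGroup(path, "obsm")
    rhdf5::h5write(t(xy), path, "obsm/spatial")
  }
  fid <- rhdf5::H5Fopen(path)
  for (grp in c("obs", "var")) {
    gid <- rhdf5::H5Gopen(fid, grp)
    rhdf5::h5writeAttribute("_index", gid, "_index")
    rhdf5::H5Gclose(gid)
  }
  rhdf5::H5Fclose(fid)
  invisible(path)
}
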