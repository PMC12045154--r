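test_that("ExpressionDataset enforces its invariants", {
  m <- toyCounts()
  ds <- ExpressionDataset(m, labels = rep(c("a", "b"), 3))
  expect_s4_class(ds, "ExpressionDataset")
  expect_identical(geneNames(ds), rownames(m))
  expect_identical(obsIds(ds), colnames(m))
  expect_identical(layerTag(ds), "raw")

  bad <- m; bad[1, 1] <- -1
  expect_error(ExpressionDataset(bad), "non-negative")
  bad <- m; rownames(bad)[2] <- rownames(bad)[1]
  expect_error(ExpressionDataset(bad), "unique")
  frac <- m; frac[1, 1] <- 0.5
  expect_error(ExpressionDataset(frac, layerTag = "raw"), "integer")
  expect_s4_class(ExpressionDataset(frac, layerTag = "normalized"),
                  "ExpressionDataset")
  expect_error(ExpressionDataset(m, labels = c("a", "b")), "length")
})

test_that("CSV reading infers shape, ids and deduplicates genes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gA,gB", "1,2", "3,4", "5,6"), path)
  ds <- readExpressionDataset(path, "csv")
  expect_identical(dim(ds), c(2L, 3L))        # 2 genes x 3 observations
  expect_identical(geneNames(ds), c("gA", "gB"))
  expect_equal(unname(exprValues(ds)["gB", ]), c(2, 4, 6))

  # explicit observation ids in a leading non-numeric column
  writeLines(c("obs_id,gA,gB", "s1,1,2", "s2,3,4"), path)
  expect_identical(obsIds(readExpressionDataset(path, "csv")),
                   c("s1", "s2"))

  # duplicated gene column: keep first, warn
  writeLines(c("gA,gB,gA", "1,2,9", "3,4,9"), path)
  expect_warning(ds2 <- readExpressionDataset(path, "csv"), "duplicated")
  expect_identical(dim(ds2)[1], 2L)
  expect_equal(unname(exprValues(ds2)["gA", ]), c(1, 3))

  writeLines(c("gA,gB", "1,2", "x,4"), path)
  expect_error(readExpressionDataset(path, "csv"), "row 2.*gA")
  expect_error(readExpressionDataset(file.path(tempdir(), "nope.csv")),
               "nope.csv")
})

test_that("mtx directory round trip preserves counts and metadata", {
  dir <- withr::local_tempdir()
  m <- toyCounts(G = 5, n = 4, seed = 3)
  ds <- ExpressionDataset(m, labels = c("a", "a", "b", "b"),
                          coords = cbind(runif(4), runif(4)))
  writeExpressionDataset(ds, dir, "mtx")
  back <- readExpressionDataset(dir, "mtx")
  expect_equal(as.matrix(exprValues(back)), m)
  expect_identical(cellLabels(back), cellLabels(ds))
  expect_equal(spatialCoords(back), spatialCoords(ds),
               ignore_attr = TRUE, tolerance = 1e-12)

  # corrupt the barcode list: length mismatch must be caught
  writeLines(c("only_one"), file.path(dir, "barcodes.tsv"))
  expect_error(readExpressionDataset(dir, "mtx"), "barcode")
})

test_that("h5ad round trip works for dense and sparse X", {
  path <- withr::local_tempfile(fileext = ".h5ad")
  m <- toyCounts(G = 6, n = 5, seed = 4)
  ds <- ExpressionDataset(m, labels = c("a", "b", "a", "b", "a"),
                          coords = cbind(seq_len(5), 5:1))
  writeExpressionDataset(ds, path, "h5ad")
  back <- readExpressionDataset(path, "h5ad")
  expect_equal(as.matrix(exprValues(back)), m)
  expect_identical(cellLabels(back), cellLabels(ds))
  expect_equal(spatialCoords(back), spatialCoords(ds),
               ignore_attr = TRUE)

  # hand-built CSR X with categorical labels, the anndata convention
  sp <- withr::local_tempfile(fileext = ".h5ad")
  rhdf5::h5createFile(sp)
  # 2 obs x 3 var: rows (1,0,2) and (0,3,0)
  rhdf5::h5createGroup(sp, "X")
  rhdf5::h5write(c(1, 2, 3), sp, "X/data")
  rhdf5::h5write(as.integer(c(0, 2, 1)), sp, "X/indices")
  rhdf5::h5write(as.integer(c(0, 2, 3)), sp, "X/indptr")
  fid <- rhdf5::H5Fopen(sp)
  gid <- rhdf5::H5Gopen(fid, "X")
  rhdf5::h5writeAttribute("csr_matrix", gid, "encoding-type")
  rhdf5::h5writeAttribute(as.integer(c(2, 3)), gid, "shape")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  rhdf5::h5createGroup(sp, "obs")
  rhdf5::h5createGroup(sp, "var")
  rhdf5::h5write(c("c1", "c2"), sp, "obs/_index")
  rhdf5::h5write(c("gX", "gY", "gZ"), sp, "var/_index")
  rhdf5::h5createGroup(sp, "obs/cell_type")
  rhdf5::h5write(c("neuron", "glia"), sp, "obs/cell_type/categories")
  rhdf5::h5write(as.integer(c(1, 0)), sp, "obs/cell_type/codes")
  rhdf5::h5closeAll()
  got <- readExpressionDataset(sp, "h5ad")
  expect_equal(unname(as.matrix(exprValues(got))),
               matrix(c(1, 0, 2, 0, 3, 0), 3, 2), ignore_attr = TRUE)
  expect_identical(geneNames(got), c("gX", "gY", "gZ"))
  expect_identical(cellLabels(got), c("glia", "neuron"))
})

test_that("intersectGenes keeps shared genes in reference order", {
  mr <- toyCounts(G = 3, n = 2); rownames(mr) <- c("A", "B", "C")
  ms <- toyCounts(G = 3, n = 4); rownames(ms) <- c("B", "C", "D")
  r <- ExpressionDataset(mr)
  s <- ExpressionDataset(ms)
  out <- intersectGenes(r, s)
  expect_identical(geneNames(out$reference), c("B", "C"))
  expect_identical(geneNames(out$spatial), c("B", "C"))
  expect_identical(ncol(out$spatial), 4L)

  # identical gene sets: unchanged content
  out2 <- intersectGenes(r, ExpressionDataset(mr[c(3, 1, 2), ]))
  expect_identical(geneNames(out2$spatial), c("A", "B", "C"))
  expect_equal(as.matrix(exprValues(out2$spatial)), mr)

  rownames(ms) <- c("X", "Y", "Z")
  expect_error(intersectGenes(r, ExpressionDataset(ms)), "no shared genes")
})

test_that("intersection preserves entries and is commutative in gene set", {
  for (seed in 1:3) {
    set.seed(seed)
    m1 <- toyCounts(G = 20, n = 30, seed = seed)
    m2 <- toyCounts(G = 20, n = 10, seed = seed + 50)
    rownames(m2) <- sprintf("g%02d", sample(1:30, 20))
    d1 <- ExpressionDataset(m1)
    d2 <- ExpressionDataset(m2)
    ab <- intersectGenes(d1, d2)
    ba <- intersectGenes(d2, d1)
    expect_setequal(geneNames(ab$reference), geneNames(ba$reference))
    shared <- geneNames(ab$reference)
    expect_equal(as.matrix(exprValues(ab$spatial)),
                 m2[shared, , drop = FALSE])
    expect_equal(as.matrix(exprValues(ab$reference)),
                 m1[shared, , drop = FALSE])
  }
})

test_that("normalizeDataset scales, logs and handles degenerate rows", {
  m <- matrix(c(1, 1, 2), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  n1 <- normalizeDataset(ExpressionDataset(m), 1e4, logTransform = FALSE)
  expect_equal(unname(as.matrix(exprValues(n1))[, 1]),
               c(2500, 2500, 5000))
  expect_identical(layerTag(n1), "normalized")

  m2 <- matrix(c(3), 1, 1, dimnames = list("g", "s"))
  n2 <- normalizeDataset(ExpressionDataset(m2), 1, logTransform = TRUE)
  expect_equal(as.numeric(exprValues(n2)), log(2))

  m3 <- cbind(m, s2 = c(0, 0, 0))
  expect_warning(n3 <- normalizeDataset(ExpressionDataset(m3), 100,
                                        logTransform = FALSE),
                 "all-zero")
  expect_equal(unname(as.matrix(exprValues(n3))[, 2]), c(0, 0, 0))
  expect_error(normalizeDataset(ExpressionDataset(m), -5), "positive")
  expect_error(normalizeDataset(n1), "raw")
})

test_that("normalization leaves already-scaled data unchanged (log off)", {
  set.seed(7)
  m <- matrix(rmultinom(5, 100, prob = runif(8)), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  ds <- ExpressionDataset(m)
  once <- normalizeDataset(ds, 100, logTransform = FALSE)
  expect_equal(as.matrix(exprValues(once)), m, tolerance = 1e-9)
})

test_that("encodeLabels uses first-appearance order", {
  ds <- ExpressionDataset(toyCounts(n = 3), labels = c("b", "a", "b"))
  enc <- encodeLabels(ds)
  expect_identical(enc$vocabulary, c("b", "a"))
  expect_identical(enc$codes, c(0L, 1L, 0L))

  one <- encodeLabels(ExpressionDataset(toyCounts(n = 3),
                                        labels = rep("x", 3)))
  expect_identical(one$vocabulary, "x")
  expect_identical(one$codes, rep(0L, 3))

  expect_error(encodeLabels(ExpressionDataset(toyCounts(n = 3),
                                              labels = c("a", "", "b"))),
               "non-empty")
  expect_error(encodeLabels(ExpressionDataset(toyCounts(n = 3))),
               "labels")
})

test_that("probability matrix CSV round-trips losslessly", {
  set.seed(11)
  raw <- matrix(rexp(8), 4, 2)
  probs <- raw / rowSums(raw)
  pm <- toyProbMatrix(probs, ids = paste0("s", 1:4),
                      types = c("neuron", "glia"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeProbabilityMatrix(pm, path)
  lines <- readLines(path)
  expect_length(lines, 5L)           # header + 4 observations
  expect_match(lines[1], "^obs_id,neuron,glia$")
  back <- readProbabilityMatrix(path)
  expect_lt(max(abs(probValues(back) - probValues(pm))), 1e-9)
  expect_identical(typeVocabulary(back), typeVocabulary(pm))

  bad <- probs; bad[1, 1] <- bad[1, 1] + 0.2
  expect_error(toyProbMatrix(bad), "sum to 1")
})
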