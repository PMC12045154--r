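test_that("cosineLambda matches the direct cosine formula", {
  # single gene [1,2,2], type a indicated by first two cells:
  # lambda = 3 / (3 * sqrt(2))
  m <- matrix(c(1, 2, 2), 1, 3, dimnames = list("g1", paste0("c", 1:3)))
  ds <- normalizedDataset(m, labels = c("a", "a", "b"))
  lam <- cosineLambda(ds)
  expect_equal(lam["g1", "a"], 3 / (3 * sqrt(2)), tolerance = 1e-12)
  expect_equal(lam["g1", "a"], 0.70711, tolerance = 1e-5)

  # gene expressed uniformly in exactly the type's cells: parallel vectors
  m2 <- matrix(c(5, 5, 0, 0), 1, 4,
               dimnames = list("g1", paste0("c", 1:4)))
  ds2 <- normalizedDataset(m2, labels = c("a", "a", "b", "b"))
  expect_equal(cosineLambda(ds2)["g1", "a"], 1, tolerance = 1e-12)

  # all-zero gene: lambda 0 for every type
  m3 <- rbind(m2, g2 = 0)
  lam3 <- cosineLambda(normalizedDataset(m3,
                                         labels = c("a", "a", "b", "b")))
  expect_equal(unname(lam3["g2", ]), c(0, 0))

  expect_error(cosineLambda(ds, labels = c("a", "b")), "length")
})

test_that("cosineLambda agrees with a brute-force oracle", {
  ds <- randomLabelledDataset(G = 20, n = 30, K = 3, seed = 5)
  lam <- cosineLambda(ds)
  expected <- oracleLambda(as.matrix(exprValues(ds)), cellLabels(ds))
  expect_equal(lam, expected[, colnames(lam)], tolerance = 1e-12)
})

test_that("cosgScore implements the penalized cosine", {
  lam <- rbind(exclusive = c(1, 0), mixed = c(0.8, 0.6))
  colnames(lam) <- c("k1", "k2")
  s1 <- cosgScore(lam, mu = 1)
  expect_equal(unname(s1["exclusive", ]), c(1, 0))
  expect_equal(s1["mixed", "k1"], 0.64 / (0.64 + 0.36), tolerance = 1e-12)
  expect_equal(s1["mixed", "k2"], 0.36 / (0.36 + 0.64), tolerance = 1e-12)

  # mu = 0 collapses to the sign of lambda for nonzero entries
  s0 <- cosgScore(lam, mu = 0)
  expect_equal(unname(s0["mixed", ]), c(1, 1))
  expect_equal(s0["exclusive", "k2"], 0)

  # negative lambda keeps its sign so anti-markers rank last
  sneg <- cosgScore(rbind(g = c(-0.5, 0.5)), mu = 1)
  expect_lt(sneg[1, 1], 0)
  expect_error(cosgScore(lam, mu = -1), "mu")
})

test_that("cosgScore is invariant to positive rescaling of a gene", {
  ds <- randomLabelledDataset(G = 15, n = 40, K = 4, seed = 9)
  m <- as.matrix(exprValues(ds))
  sc1 <- cosgScore(cosineLambda(ds), mu = 1)
  m[3, ] <- m[3, ] * 17.5
  sc2 <- cosgScore(cosineLambda(normalizedDataset(m,
                                                  labels = cellLabels(ds))),
                   mu = 1)
  expect_equal(sc1, sc2, tolerance = 1e-12)
})

test_that("fuseAndSelect ranks, unions and clamps as specified", {
  cosg <- rbind(gA = c(0.9, 0.1), gB = c(0.2, 0.8), gC = c(0.5, 0.5))
  colnames(cosg) <- c("k1", "k2")

  # per-type n = 1: union of per-type argmaxes, reference gene order
  sel <- fuseAndSelect(cosg, rep(1, 3), nTop = 1, perType = TRUE)
  expect_identical(sel$panel, c("gA", "gB"))

  # brute force over all genes confirms the per-type argmaxes
  expect_identical(rownames(cosg)[which.max(cosg[, 1])], "gA")
  expect_identical(rownames(cosg)[which.max(cosg[, 2])], "gB")

  # nTop = gene count: whole panel
  expect_identical(
    fuseAndSelect(cosg, rep(1, 3), nTop = 3, perType = FALSE)$panel,
    c("gA", "gB", "gC"))
  expect_warning(big <- fuseAndSelect(cosg, rep(1, 3), nTop = 10),
                 "exceeds")
  expect_length(big$panel, 3L)

  # attention shifts the ranking: crush gA and k1's best becomes gC
  att <- c(gA = 0.01, gB = 1, gC = 1)
  sel2 <- fuseAndSelect(cosg, att, nTop = 1, perType = TRUE)
  expect_identical(sel2$panel, c("gB", "gC"))
})

test_that("uniform attention reduces the fused ranking to COSG exactly", {
  for (seed in 1:3) {
    ds <- randomLabelledDataset(G = 50, n = 60, K = 4, seed = seed)
    cosg <- cosgScore(cosineLambda(ds), mu = 1)
    sel <- fuseAndSelect(cosg, rep(1 / 50, 50), nTop = 50, perType = TRUE)
    genes <- rownames(cosg)
    for (k in seq_len(ncol(cosg))) {
      expect_identical(order(-sel$fused[, k], genes),
                       order(-cosg[, k], genes))
    }
  }
})

test_that("attention weights are a probability vector and deterministic", {
  ds <- normalizeDataset(oneMarkerDataset(G = 30, nPerType = 60, seed = 2))
  w1 <- trainAttention(ds, epochs = 5, seed = 42)
  w2 <- trainAttention(ds, epochs = 5, seed = 42)
  expect_identical(w1, w2)
  expect_equal(sum(w1), 1, tolerance = 1e-12)
  expect_true(all(w1 >= 0))
  expect_identical(names(w1), geneNames(ds))

  one <- normalizedDataset(matrix(1:4, 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("c1", "c2"))),
                           labels = c("x", "x"))
  expect_error(trainAttention(one), ">=2 classes")
})

test_that("permuting gene order permutes attention weights identically", {
  ds <- normalizeDataset(oneMarkerDataset(G = 25, nPerType = 40, seed = 3))
  w <- trainAttention(ds, epochs = 5, seed = 7)
  set.seed(99)
  perm <- sample(nrow(ds))
  dsPerm <- ds[perm, ]
  wPerm <- trainAttention(dsPerm, epochs = 5, seed = 7)
  expect_identical(wPerm, w[perm])
})

test_that("selectFeatureGenes is seed-deterministic and shuffle-stable", {
  ds <- normalizeDataset(simulateReference(
    simulationConfig(K = 3, G = 90, markersPerType = 10, nRefPerType = 50,
                     seed = 4)))
  ctl <- list(epochs = 5, seed = 0)
  gst1 <- selectFeatureGenes(ds, nTop = 10, attentionControl = ctl)
  gst2 <- selectFeatureGenes(ds, nTop = 10, attentionControl = ctl)
  expect_identical(genePanel(gst1), genePanel(gst2))

  set.seed(123)
  shuf <- ds[, sample(ncol(ds))]
  gst3 <- selectFeatureGenes(shuf, nTop = 10, attentionControl = ctl)
  expect_identical(genePanel(gst3), genePanel(gst1))

  # with strong disjoint marker blocks the selected panel is the marker set
  expect_gte(mean(genePanel(gst1) %in% sprintf("g%04d", 1:30)), 0.9)

  df <- as.data.frame(gst1)
  expect_identical(colnames(df), c("gene", "cell_type", "lambda",
                                   "cosg_score", "attention_weight",
                                   "fused_score"))
  expect_identical(nrow(df), 90L * 3L)
})
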