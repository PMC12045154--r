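test_that("metrics reproduce their printed examples", {
  expect_equal(metricCos(c(1, 2, 2), c(1, 1, 0)), 0.70711,
               tolerance = 1e-5)
  p <- c(0.3, 0.5, 0.2)
  expect_equal(metricCos(p, p), 1, tolerance = 1e-12)
  expect_equal(metricCos(c(1, 0), c(0, 1)), 0)
  expect_equal(metricCos(c(0, 0), c(0, 0)), 0)   # all-zero convention

  expect_equal(metricPPMC(c(1, 2, 3), 2 * c(1, 2, 3)), 1)
  expect_equal(metricPPMC(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(metricPPMC(c(1, 2, 3), c(1, 3, 2)), 0.5, tolerance = 1e-12)
  expect_warning(z <- metricPPMC(c(1, 1), c(0, 2)), "zero-variance")
  expect_equal(z, 0)

  expect_equal(metricSSIM(p, p), 1, tolerance = 1e-12)
  expect_equal(metricSSIM(c(0, 0), c(0, 0)), 1)  # degenerate C-term ratio
  expect_equal(metricSSIM(c(0, 1), c(1, 0)), oracleSSIM(c(0, 1), c(1, 0)),
               tolerance = 1e-12)

  expect_equal(metricKL(p, p), 0)
  expect_equal(metricKL(c(0.25, 0.75), c(0.5, 0.5)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-9)
  expect_true(is.finite(metricKL(c(0, 1), c(0.5, 0.5))))

  expect_equal(metricJS(p, p), 0)
  expect_equal(metricJS(c(1, 0), c(0, 1)), log(2), tolerance = 1e-9)
})

test_that("metrics agree with independent brute-force oracles", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    p <- runif(n)
    r <- runif(n)
    expect_equal(metricCos(p, r), oracleCos(p, r), tolerance = 1e-10)
    expect_equal(metricPPMC(p, r), oraclePearson(p, r), tolerance = 1e-10)
    expect_equal(metricSSIM(p, r), oracleSSIM(p, r), tolerance = 1e-10)
    expect_equal(metricKL(p, r), oracleKL(p, r), tolerance = 1e-10)
    expect_equal(metricJS(p, r), oracleJS(p, r), tolerance = 1e-10)
  }
})

test_that("divergences respect their analytic bounds on random simplices", {
  set.seed(17)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    p <- rexp(k); p <- p / sum(p)
    r <- rexp(k); r <- r / sum(r)
    expect_gte(metricKL(p, r), 0)
    js <- metricJS(p, r)
    expect_gte(js, 0)
    expect_lte(js, log(2) + 1e-12)
    expect_equal(js, metricJS(r, p), tolerance = 1e-12)
    s <- metricSSIM(p, r)
    expect_gte(s, -1)
    expect_lte(s, 1 + 1e-12)
  }
})

test_that("buildReferenceMap covers annotation and marker modes", {
  sp <- normalizedDataset(
    matrix(c(0, 2, 4, 1, 1, 1), 2, 3, byrow = TRUE,
           dimnames = list(c("mk1", "other"), c("s1", "s2", "s3"))))
  ann <- buildReferenceMap(sp, labels = c("a", "b", "a"))
  expect_identical(ann@source, "annotation_onehot")
  expect_equal(unname(mapValues(ann)),
               rbind(c(1, 0), c(0, 1), c(1, 0)))

  mk <- buildReferenceMap(sp, markers = list(ct1 = "mk1"))
  expect_identical(mk@source, "marker_gene_sum")
  expect_equal(unname(mapValues(mk)[, 1]), c(0, 0.5, 1))

  expect_error(buildReferenceMap(sp, markers = list(ct1 = "absent")),
               "ct1")
})

test_that("aggregateMetrics averages per-type metrics", {
  onehot <- rbind(c(1, 0), c(0, 1), c(1, 0))
  rownames(onehot) <- paste0("s", 1:3)
  colnames(onehot) <- c("a", "b")
  pm <- toyProbMatrix(onehot)
  ref <- new("ReferenceMap", values = onehot, source = "annotation_onehot")
  agg <- aggregateMetrics(pm, ref)
  expect_equal(unname(agg[c("COS", "PPMC", "SSIM")]), c(1, 1, 1),
               tolerance = 1e-9)
  expect_equal(unname(agg[c("KL", "JS")]), c(0, 0), tolerance = 1e-9)

  # one of two types perfect, the other orthogonal: COS aggregate 0.5
  orthRef <- cbind(a = onehot[, 1], b = onehot[, 1])
  rownames(orthRef) <- rownames(onehot)
  half <- aggregateMetrics(
    pm, new("ReferenceMap", values = orthRef,
            source = "annotation_onehot"))
  expect_equal(unname(half["COS"]), 0.5, tolerance = 1e-9)

  expect_error(aggregateMetrics(pm, ref@values[, 1, drop = FALSE]),
               "shapes differ")
})

test_that("matching the true one-hot beats a permuted reference", {
  sim <- simulateSpatial(simulationConfig(K = 3, G = 60,
                                          markersPerType = 10,
                                          nRefPerType = 10, nSpatial = 60,
                                          seed = 6))
  truth <- mapValues(groundTruthReferenceMap(sim))
  pm <- toyProbMatrix(0.9 * truth + 0.1 / 3)   # near-perfect prediction
  permuted <- truth[, c(2, 3, 1)]
  colnames(permuted) <- colnames(truth)
  cosTrue <- aggregateMetrics(pm, truth)["COS"]
  cosPerm <- aggregateMetrics(pm, permuted)["COS"]
  expect_gt(cosTrue, cosPerm)
})

test_that("accScore implements rank-averaging with the stated direction", {
  vals <- rbind(
    DSCT  = c(COS = 0.9, PPMC = 0.8, SSIM = 0.9, KL = 0.1, JS = 0.05),
    other = c(COS = 0.5, PPMC = 0.6, SSIM = 0.7, KL = 0.5, JS = 0.20),
    worst = c(COS = 0.2, PPMC = 0.1, SSIM = 0.3, KL = 0.9, JS = 0.40))
  sc <- accScore(vals)
  expect_equal(unname(sc$score["DSCT"]), 1.0)
  expect_equal(unname(sc$score["worst"]), 1 / 3)

  # two identical methods share average rank 1.5 of 2: score 0.75 each
  two <- vals[c(1, 1), ]
  rownames(two) <- c("m1", "m2")
  sc2 <- accScore(two)
  expect_equal(unname(sc2$score), c(0.75, 0.75))

  # strictly monotone transform of one metric leaves every rank unchanged
  mono <- vals
  mono[, "KL"] <- exp(5 * mono[, "KL"])
  expect_equal(accScore(mono)$score, sc$score)

  expect_error(accScore(vals[1, , drop = FALSE]), ">= 2 methods")
  expect_error(accScore(vals[, c("COS", "PPMC")]), "missing")
})

test_that("confusionMatrix counts overlap fractions", {
  perf <- confusionMatrix(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(unname(perf$matrix), diag(2))
  expect_equal(perf$accuracy, 1)

  const <- confusionMatrix(rep("a", 4), c("a", "b", "a", "b"))
  expect_equal(unname(const$matrix[, "a"]), c(1, 1))

  toy <- confusionMatrix(c("a", "a", "b", "b"), c("a", "a", "a", "b"))
  expect_equal(toy$accuracy, 0.75)
  expect_error(confusionMatrix("a", c("a", "b")), "length")
})

test_that("proportionSimilarity compares composition vectors", {
  P <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  pm <- toyProbMatrix(P, types = c("a", "b"))
  same <- proportionSimilarity(pm, c(a = 0.7, b = 0.3))
  expect_equal(unname(same), c(1, 1), tolerance = 1e-9)

  expect_warning(
    unif <- proportionSimilarity(toyProbMatrix(rbind(c(0.5, 0.5),
                                                     c(0.5, 0.5)),
                                               types = c("a", "b")),
                                 c(a = 0.5, b = 0.5)),
    "zero-variance")
  expect_equal(unname(unif), c(0, 1), tolerance = 1e-9)

  toy <- proportionSimilarity(pm, c(a = 0.6, b = 0.4))
  expect_equal(unname(toy["PPMC"]),
               oraclePearson(c(0.7, 0.3), c(0.6, 0.4)), tolerance = 1e-9)
  expect_equal(unname(toy["COS"]), oracleCos(c(0.7, 0.3), c(0.6, 0.4)),
               tolerance = 1e-9)

  hard <- proportionSimilarity(pm, c(a = 1, b = 0), mode = "hard")
  expect_equal(unname(hard["COS"]), 1, tolerance = 1e-9)
})
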