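# Ground-truth simulation of paired reference / spatial data sets:
# negative-binomial counts with disjoint marker blocks per cell type, and
# a layered spatial architecture at single-cell or multi-cell spot
# resolution.

# Per-gene, per-type NB means: baseMean everywhere, elevated foldChange-
# fold on the type's disjoint marker block.
.typeMeans <- function(cfg) {
  mu <- matrix(cfg@baseMean, cfg@G, cfg@K)
  for (k in seq_len(cfg@K)) {
    rows <- ((k - 1L) * cfg@markersPerType + 1L):(k * cfg@markersPerType)
    mu[rows, k] <- cfg@baseMean * cfg@foldChange
  }
  dimnames(mu) <- list(.simGeneNames(cfg), .simTypeNames(cfg))
  mu
}

.simGeneNames <- function(cfg) sprintf("g%04d", seq_len(cfg@G))
.simTypeNames <- function(cfg) sprintf("type%02d", seq_len(cfg@K))

# NB counts for one type: genes x n matrix.
.drawCounts <- function(mu, n, dispersion) {
  matrix(stats::rnbinom(length(mu) * n, mu = mu, size = 1 / dispersion),
         nrow = length(mu), ncol = n)
}

#' Simulate an annotated single-cell reference
#'
#' Draws `nRefPerType` cells per type from the negative-binomial model of
#' the configuration; deterministic given `cfg@seed`.
#'
#' @param cfg a [simulationConfig()].
#' @return labelled raw [ExpressionDataset] with
#'   `K * nRefPerType` cells.
#' @export
simulateReference <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  mu <- .typeMeans(cfg)
  .withSeed(cfg@seed, {
    blocks <- lapply(seq_len(cfg@K), function(k)
      .drawCounts(mu[, k], cfg@nRefPerType, cfg@dispersion))
    m <- do.call(cbind, blocks)
    labels <- rep(.simTypeNames(cfg), each = cfg@nRefPerType)
    dimnames(m) <- list(rownames(mu),
                        sprintf("ref_%05d", seq_len(ncol(m))))
    ExpressionDataset(m, labels = labels, layerTag = "raw")
  })
}

# Type mixing weights at height y: the "layers" layout assigns pure bands
# for single-cell data; multi-cell spots draw from a Gaussian kernel over
# band centers (sd = a quarter band width), giving pure interiors and
# mixed band boundaries.
.bandOf <- function(y, K) pmin(pmax(ceiling(y * K), 1L), K)

.mixWeights <- function(y, K) {
  centers <- (seq_len(K) - 0.5) / K
  sigma <- 1 / (4 * K)
  w <- exp(-0.5 * ((y - centers) / sigma)^2)
  w / sum(w)
}

#' Simulate a spatial data set with known ground truth
#'
#' Observations are placed uniformly in the unit square. Under the
#' `"layers"` layout cell types occupy `K` horizontal bands; the
#' `"random"` layout draws types uniformly. With `cellsPerSpot = 1` each
#' observation is a single cell with an exact label (the proportion matrix
#' is one-hot); with `cellsPerSpot > 1` each spot sums the counts of that
#' many cells drawn from the local type mixture, and the realized mixing
#' proportions are recorded.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `dataset` (raw [ExpressionDataset] with coordinates
#'   and, at single-cell resolution, labels), `proportions`
#'   (observations x K true mixing proportions, rows summing to 1) and
#'   `labels` (per-observation dominant type; exact at single-cell
#'   resolution, ties to the lowest type index otherwise).
#' @export
simulateSpatial <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  mu <- .typeMeans(cfg)
  typeNames <- colnames(mu)
  .withSeed(cfg@seed + 1L, {
    n <- cfg@nSpatial
    coords <- cbind(x = stats::runif(n), y = stats::runif(n))
    prop <- matrix(0, n, cfg@K,
                   dimnames = list(sprintf("spot_%05d", seq_len(n)),
                                   typeNames))
    m <- matrix(0L, cfg@G, n)
    for (i in seq_len(n)) {
      if (cfg@cellsPerSpot == 1L) {
        k <- if (cfg@layout == "layers") .bandOf(coords[i, "y"], cfg@K)
             else sample.int(cfg@K, 1L)
        types <- k
      } else {
        w <- if (cfg@layout == "layers") .mixWeights(coords[i, "y"], cfg@K)
             else rep(1 / cfg@K, cfg@K)
        types <- sample.int(cfg@K, cfg@cellsPerSpot, replace = TRUE,
                            prob = w)
      }
      counts <- rowSums(.drawCounts(mu[, types[1L]], 1L, cfg@dispersion))
      if (length(types) > 1L)
        for (t2 in types[-1L])
          counts <- counts + .drawCounts(mu[, t2], 1L, cfg@dispersion)
      m[, i] <- counts
      tab <- tabulate(types, nbins = cfg@K)
      prop[i, ] <- tab / length(types)
    }
    dimnames(m) <- list(rownames(mu), rownames(prop))
    labels <- typeNames[max.col(prop, ties.method = "first")]
    ds <- ExpressionDataset(m,
                            labels = if (cfg@cellsPerSpot == 1L) labels
                                     else NULL,
                            coords = coords, layerTag = "raw")
    list(dataset = ds, proportions = prop,
         labels = stats::setNames(labels, rownames(prop)))
  })
}

#' Wrap simulation ground truth as a ReferenceMap
#'
#' One-hot at single-cell resolution, true mixing proportions for
#' multi-cell spots; vocabulary order follows the configuration's type
#' order.
#'
#' @param sim the list returned by [simulateSpatial()].
#' @return A [ReferenceMap].
#' @export
groundTruthReferenceMap <- function(sim) {
  stopifnot(is.list(sim), !is.null(sim$proportions))
  onehot <- all(sim$proportions %in% c(0, 1))
  new("ReferenceMap", values = sim$proportions,
      source = if (onehot) "annotation_onehot" else "true_proportions")
}
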