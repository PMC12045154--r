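# The DSCT classifier: a lightweight five-hidden-layer fully connected
# network whose first hidden activations are added to the fifth hidden
# pre-activations (an initial -> terminal residual connection), trained
# with cross-entropy loss and the Adagrad optimizer.

#' Describe the DSCT network architecture
#'
#' Defaults: five hidden layers of widths (256, 128, 64, 128, 256) — a
#' symmetric bottleneck whose equal first/last widths carry the residual
#' connection from hidden layer 1 to hidden layer 5 — ReLU activations
#' and dropout 0.1.
#'
#' @param inputDim panel size (>= 1).
#' @param outputDim number of cell types (>= 2).
#' @param hiddenDims exactly five positive widths.
#' @param residual pair (source, destination) of hidden layer indices;
#'   source precedes destination and both widths must match.
#' @param activation only `"relu"` is implemented.
#' @param dropout dropout rate in \[0, 1).
#' @return a `networkSpec` list.
#' @export
buildNetwork <- function(inputDim, outputDim,
                         hiddenDims = c(256L, 128L, 64L, 128L, 256L),
                         residual = c(1L, 5L), activation = "relu",
                         dropout = 0.1) {
  if (inputDim < 1L) .stopf("'inputDim' must be >= 1")
  if (outputDim < 2L) .stopf("'outputDim' must be >= 2")
  if (length(hiddenDims) != 5L || any(hiddenDims < 1L))
    .stopf("'hiddenDims' must give exactly 5 positive widths")
  if (length(residual) != 2L || residual[1L] >= residual[2L] ||
      residual[1L] < 1L || residual[2L] > 5L)
    .stopf("'residual' must be (source, destination) with source < destination in 1..5")
  if (hiddenDims[residual[1L]] != hiddenDims[residual[2L]])
    .stopf("residual source and destination widths must match (%d vs %d)",
           hiddenDims[residual[1L]], hiddenDims[residual[2L]])
  if (!identical(activation, "relu"))
    .stopf("only 'relu' activation is implemented")
  if (dropout < 0 || dropout >= 1)
    .stopf("'dropout' must lie in [0, 1)")
  list(inputDim = as.integer(inputDim), outputDim = as.integer(outputDim),
       hiddenDims = as.integer(hiddenDims),
       residual = as.integer(residual), activation = activation,
       dropout = as.numeric(dropout))
}

#' Training hyper-parameters for the DSCT classifier
#'
#' @param learningRate Adagrad learning rate (default 0.01).
#' @param epochs training epochs (default 100).
#' @param batchSize mini-batch size (default 128).
#' @param validationFraction stratified validation fraction in \[0, 0.5\];
#'   the parameters with the best validation loss are retained.
#' @param seed RNG seed governing the split, batch order, initialization
#'   and dropout; identical configs give bitwise-identical results.
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping; 0 disables early stopping.
#' @return a `trainingConfig` list.
#' @export
trainingConfig <- function(learningRate = 0.01, epochs = 100L,
                           batchSize = 128L, validationFraction = 0.1,
                           seed = 0L, earlyStopPatience = 10L) {
  if (learningRate < 0) .stopf("'learningRate' must be >= 0")
  if (epochs < 0L) .stopf("'epochs' must be >= 0")
  if (batchSize < 1L) .stopf("'batchSize' must be >= 1")
  if (validationFraction < 0 || validationFraction > 0.5)
    .stopf("'validationFraction' must lie in [0, 0.5]")
  if (earlyStopPatience < 0L) .stopf("'earlyStopPatience' must be >= 0")
  list(learningRate = as.numeric(learningRate), epochs = as.integer(epochs),
       batchSize = as.integer(batchSize),
       validationFraction = as.numeric(validationFraction),
       seed = as.integer(seed),
       earlyStopPatience = as.integer(earlyStopPatience))
}

#' Mean cross-entropy of predicted probabilities
#'
#' Mean over observations of `-ln p(true class)`, probabilities clipped
#' below at 1e-12.
#'
#' @param probabilities row-stochastic observations x classes matrix.
#' @param trueLabels 0-based integer class codes (as from
#'   [encodeLabels()]).
#' @return non-negative scalar.
#' @export
crossEntropy <- function(probabilities, trueLabels) {
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != length(trueLabels))
    .stopf("shape mismatch: %d rows vs %d labels",
           nrow(probabilities), length(trueLabels))
  if (any(trueLabels < 0L) || any(trueLabels >= ncol(probabilities)))
    .stopf("labels must lie in [0, %d)", ncol(probabilities))
  p <- probabilities[cbind(seq_len(nrow(probabilities)),
                           as.integer(trueLabels) + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Train the DSCT classifier on a labelled reference
#'
#' The reference is restricted and reordered to the gene panel, expression
#' is standardized per gene (zero mean, unit variance, statistics stored
#' for re-use at prediction time) and the residual MLP is fitted by
#' mini-batch Adagrad on cross-entropy loss. A stratified validation split
#' monitors generalization; the parameters with the lowest validation loss
#' are retained.
#'
#' @param reference normalized, labelled [ExpressionDataset].
#' @param panel ordered gene names to train on (default: all reference
#'   genes); every panel gene must be present.
#' @param labels optional labels (default from `reference`).
#' @param networkSpec from [buildNetwork()]; default architecture when
#'   `NULL`.
#' @param config from [trainingConfig()].
#' @return A [TrainedClassifier].
#' @export
trainClassifier <- function(reference, panel = geneNames(reference),
                            labels = NULL, networkSpec = NULL,
                            config = trainingConfig()) {
  stopifnot(is(reference, "ExpressionDataset"))
  if (layerTag(reference) != "normalized")
    .stopf("trainClassifier expects a normalized reference")
  missing <- setdiff(panel, geneNames(reference))
  if (length(missing))
    .stopf("panel genes absent from reference: %s",
           paste(missing, collapse = ", "))
  enc <- .resolveLabels(reference, labels)
  K <- length(enc$vocabulary)
  if (K < 2L) .stopf("training requires >= 2 cell types")
  X <- t(.denseMatrix(exprValues(reference[panel, ])))   # cells x panel
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2L, stats::sd), 1e-8)
  X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  if (is.null(networkSpec))
    networkSpec <- buildNetwork(length(panel), K)
  if (networkSpec$inputDim != length(panel) ||
      networkSpec$outputDim != K)
    .stopf("network spec dimensions (%d -> %d) do not match panel/classes (%d -> %d)",
           networkSpec$inputDim, networkSpec$outputDim, length(panel), K)
  y <- enc$codes + 1L

  fit <- .withSeed(config$seed, {
    params <- .mlpInit(networkSpec)
    acc <- .adagradInit(params)
    split <- .stratifiedSplit(enc$codes, config$validationFraction)
    trainIdx <- split$train
    valIdx <- split$val
    hasVal <- length(valIdx) > 0L
    best <- params
    bestLoss <- Inf
    sinceBest <- 0L
    hist <- vector("list", config$epochs)
    nEpochs <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(trainIdx)
      starts <- seq(1L, length(ord), by = config$batchSize)
      for (bi in seq_along(starts)) {
        bIdx <- ord[starts[bi]:min(starts[bi] + config$batchSize - 1L,
                                   length(ord))]
        st <- .mlpForward(X[bIdx, , drop = FALSE], params, networkSpec,
                          train = TRUE, keepState = TRUE)
        loss <- crossEntropy(st$probs, y[bIdx] - 1L)
        if (!is.finite(loss))
          .stopf("training loss became non-finite at epoch %d, batch %d",
                 ep, bi)
        grads <- .mlpBackward(st, y[bIdx], params, networkSpec)
        upd <- .adagradStep(params, grads, acc, config$learningRate)
        params <- upd$params
        acc <- upd$acc
      }
      pTrain <- .mlpForward(X[trainIdx, , drop = FALSE], params,
                            networkSpec)
      trainLoss <- crossEntropy(pTrain, y[trainIdx] - 1L)
      trainAcc <- mean(max.col(pTrain, ties.method = "first") ==
                         y[trainIdx])
      if (hasVal) {
        pVal <- .mlpForward(X[valIdx, , drop = FALSE], params, networkSpec)
        valLoss <- crossEntropy(pVal, y[valIdx] - 1L)
        valAcc <- mean(max.col(pVal, ties.method = "first") == y[valIdx])
      } else {
        valLoss <- NA_real_
        valAcc <- NA_real_
      }
      hist[[ep]] <- data.frame(epoch = ep, trainLoss = trainLoss,
                               trainAccuracy = trainAcc, valLoss = valLoss,
                               valAccuracy = valAcc)
      nEpochs <- ep
      monitor <- if (hasVal) valLoss else trainLoss
      if (monitor < bestLoss) {
        bestLoss <- monitor
        best <- params
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (config$earlyStopPatience > 0L &&
            sinceBest >= config$earlyStopPatience)
          break
      }
    }
    history <- if (nEpochs > 0L) do.call(rbind, hist[seq_len(nEpochs)])
      else data.frame(epoch = integer(), trainLoss = numeric(),
                      trainAccuracy = numeric(), valLoss = numeric(),
                      valAccuracy = numeric())
    list(params = if (is.finite(bestLoss)) best else params,
         history = history)
  })

  out <- new("TrainedClassifier", networkSpec = networkSpec,
             weights = fit$params, panel = as.character(panel),
             vocabulary = enc$vocabulary,
             geneCenter = stats::setNames(ctr, panel),
             geneScale = stats::setNames(scl, panel),
             history = fit$history, trainingConfig = config)
  validObject(out)
  out
}

#' Predict cell-type probabilities for spatial observations
#'
#' Restricts the spatial data to the model's gene panel (every panel gene
#' must be present — run [intersectGenes()] before selecting the panel),
#' re-applies the reference standardization and performs a forward pass;
#' rows of the result sum to 1.
#'
#' @param model a [TrainedClassifier].
#' @param spatial normalized [ExpressionDataset].
#' @return A [CellTypeProbabilityMatrix].
#' @export
predictCellTypes <- function(model, spatial) {
  stopifnot(is(model, "TrainedClassifier"),
            is(spatial, "ExpressionDataset"))
  if (layerTag(spatial) != "normalized")
    .stopf("predictCellTypes expects a normalized spatial data set")
  missing <- setdiff(model@panel, geneNames(spatial))
  if (length(missing))
    .stopf("panel genes missing from spatial data: %s",
           paste(missing, collapse = ", "))
  X <- t(.denseMatrix(exprValues(spatial[model@panel, ])))
  X <- sweep(sweep(X, 2L, model@geneCenter), 2L, model@geneScale, "/")
  probs <- .mlpForward(X, model@weights, model@networkSpec)
  dimnames(probs) <- list(obsIds(spatial), model@vocabulary)
  CellTypeProbabilityMatrix(probs)
}

#' Hard labels from a probability matrix
#'
#' Argmax per row; ties resolve to the lowest vocabulary index.
#'
#' @param pm a [CellTypeProbabilityMatrix].
#' @return named character vector of cell types per observation.
#' @export
hardLabels <- function(pm) {
  stopifnot(is(pm, "CellTypeProbabilityMatrix"))
  m <- probValues(pm)
  stats::setNames(colnames(m)[max.col(m, ties.method = "first")],
                  rownames(m))
}

#' Persist / restore a trained classifier
#'
#' The model directory holds `model.json` (format tag, architecture,
#' panel, vocabulary, standardization statistics, training config and
#' history) and `weights.rds` (the learned tensors).
#'
#' @param model a [TrainedClassifier].
#' @param dir model directory.
#' @return `saveClassifier`: `dir` invisibly; `loadClassifier`: the model.
#' @export
saveClassifier <- function(model, dir) {
  stopifnot(is(model, "TrainedClassifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "dsct-model/1",
               networkSpec = model@networkSpec,
               panel = model@panel,
               vocabulary = model@vocabulary,
               trainingConfig = model@trainingConfig,
               history = model@history)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  # learned tensors and standardization statistics kept at full binary
  # precision so a reloaded model predicts bit-identically
  saveRDS(list(weights = model@weights,
               geneCenter = model@geneCenter,
               geneScale = model@geneScale),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(dir) {
  metaPath <- file.path(dir, "model.json")
  if (!file.exists(metaPath)) .stopf("no model.json under %s", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$format, "dsct-model/1"))
    .stopf("unsupported model format: %s", meta$format)
  spec <- meta$networkSpec
  spec <- buildNetwork(spec$inputDim, spec$outputDim, spec$hiddenDims,
                       spec$residual, spec$activation, spec$dropout)
  tensors <- readRDS(file.path(dir, "weights.rds"))
  hist <- as.data.frame(meta$history)
  cfg <- do.call(trainingConfig, meta$trainingConfig)
  new("TrainedClassifier", networkSpec = spec, weights = tensors$weights,
      panel = as.character(meta$panel),
      vocabulary = as.character(meta$vocabulary),
      geneCenter = tensors$geneCenter, geneScale = tensors$geneScale,
      history = hist, trainingConfig = cfg)
}
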