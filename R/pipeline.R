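# End-to-end orchestration: shared-gene filtering -> normalization ->
# ACOSG feature selection -> classifier training -> prediction ->
# optional evaluation, with a single resolved configuration written next
# to every run's outputs.

#' Assemble a fully resolved pipeline configuration
#'
#' Every default is materialized so the written config states exactly what
#' ran; a run is reproducible from its resolved config alone.
#'
#' @param reference,spatial input paths (csv / mtx directory / h5ad) —
#'   or `NULL` when data sets are passed to [runPipeline()] directly.
#' @param outDir output directory.
#' @param labelColumn obs column with cell types (h5ad input).
#' @param targetSum,logTransform normalization settings
#'   (see [normalizeDataset()]).
#' @param mu,nTop,perType ACOSG settings (see [selectFeatureGenes()]).
#' @param attentionEpochs,attentionLearningRate attention-net settings.
#' @param hiddenDims,residualFrom,residualTo,dropout network overrides
#'   (see [buildNetwork()]).
#' @param learningRate,epochs,batchSize,validationFraction,earlyStopPatience
#'   training settings (see [trainingConfig()]).
#' @param evaluate compute an evaluation report when the spatial data
#'   carries annotations.
#' @param seed global seed; attention and classifier seeds derive from it.
#' @return a `dsctRunConfig` list.
#' @export
runConfig <- function(reference = NULL, spatial = NULL, outDir = "dsct_out",
                      labelColumn = "cell_type", targetSum = 1e4,
                      logTransform = TRUE, mu = 1, nTop = 50,
                      perType = TRUE, attentionEpochs = 30,
                      attentionLearningRate = 0.01,
                      hiddenDims = c(256L, 128L, 64L, 128L, 256L),
                      residualFrom = 1L, residualTo = 5L, dropout = 0.1,
                      learningRate = 0.01, epochs = 100L, batchSize = 128L,
                      validationFraction = 0.1, earlyStopPatience = 10L,
                      evaluate = TRUE, seed = 0L) {
  cfg <- list(reference = reference, spatial = spatial, outDir = outDir,
              labelColumn = labelColumn, targetSum = targetSum,
              logTransform = logTransform, mu = mu, nTop = nTop,
              perType = perType, attentionEpochs = attentionEpochs,
              attentionLearningRate = attentionLearningRate,
              hiddenDims = as.integer(hiddenDims),
              residualFrom = as.integer(residualFrom),
              residualTo = as.integer(residualTo), dropout = dropout,
              learningRate = learningRate, epochs = as.integer(epochs),
              batchSize = as.integer(batchSize),
              validationFraction = validationFraction,
              earlyStopPatience = as.integer(earlyStopPatience),
              evaluate = evaluate, seed = as.integer(seed))
  class(cfg) <- c("dsctRunConfig", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a `dsctRunConfig`.
#' @param path YAML file path.
#' @return `writeRunConfig`: `path` invisibly; `readRunConfig`: the
#'   config with all defaults materialized.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "dsctRunConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    .stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(runConfig, raw)
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e)
    .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  log(sprintf("stage %-14s %8.2f s", name,
              proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full DSCT pipeline
#'
#' Executes shared-gene filtering, normalization, ACOSG feature selection,
#' classifier training, prediction and (optionally) evaluation, writing
#' the probability matrix, hard labels, gene panel and scores, model
#' directory, log and resolved configuration under `cfg$outDir`.
#'
#' @param cfg a [runConfig()] (or path to a YAML config).
#' @param reference,spatial optional in-memory [ExpressionDataset]
#'   objects overriding the config paths.
#' @return invisibly, a list with `probabilities`
#'   ([CellTypeProbabilityMatrix]), `labels`, `model`, `scores`
#'   ([GeneScoreTable]) and `report` (an [EvaluationReport]-style list or
#'   `NULL`), alongside the files in `cfg$outDir`.
#' @export
runPipeline <- function(cfg, reference = NULL, spatial = NULL) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(inherits(cfg, "dsctRunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$outDir, "log.txt")
  logLines <- character(0)
  log <- function(msg) {
    logLines <<- c(logLines, sprintf("[%s] %s",
                                     format(Sys.time(), "%H:%M:%S"), msg))
  }
  log(sprintf("DSCT pipeline, package version %s, seed %d",
              as.character(utils::packageVersion("DSCT")), cfg$seed))

  ref <- .stage("read", log, {
    if (!is.null(reference)) reference
    else if (is.null(cfg$reference)) .stopf("no reference data given")
    else readExpressionDataset(cfg$reference, labelCol = cfg$labelColumn)
  })
  sp <- .stage("read_spatial", log, {
    if (!is.null(spatial)) spatial
    else if (is.null(cfg$spatial)) .stopf("no spatial data given")
    else readExpressionDataset(cfg$spatial, labelCol = cfg$labelColumn)
  })
  if (is.null(cellLabels(ref)))
    .stopf("stage 'read' failed: reference carries no cell-type labels")

  shared <- .stage("intersect", log, intersectGenes(ref, sp))
  norm <- .stage("normalize", log, {
    list(reference = normalizeDataset(shared$reference, cfg$targetSum,
                                      cfg$logTransform),
         spatial = normalizeDataset(shared$spatial, cfg$targetSum,
                                    cfg$logTransform))
  })
  scores <- .stage("acosg", log, {
    selectFeatureGenes(norm$reference, mu = cfg$mu, nTop = cfg$nTop,
                       perType = cfg$perType,
                       attentionControl = list(
                         epochs = cfg$attentionEpochs,
                         learningRate = cfg$attentionLearningRate,
                         seed = cfg$seed))
  })
  model <- .stage("train", log, {
    K <- length(unique(cellLabels(norm$reference)))
    spec <- buildNetwork(length(genePanel(scores)), K,
                         hiddenDims = cfg$hiddenDims,
                         residual = c(cfg$residualFrom, cfg$residualTo),
                         dropout = cfg$dropout)
    trainClassifier(norm$reference, panel = genePanel(scores),
                    networkSpec = spec,
                    config = trainingConfig(
                      learningRate = cfg$learningRate,
                      epochs = cfg$epochs, batchSize = cfg$batchSize,
                      validationFraction = cfg$validationFraction,
                      seed = cfg$seed,
                      earlyStopPatience = cfg$earlyStopPatience))
  })
  pm <- .stage("predict", log, predictCellTypes(model, norm$spatial))
  labels <- hardLabels(pm)

  report <- NULL
  if (isTRUE(cfg$evaluate) && !is.null(cellLabels(sp))) {
    report <- .stage("evaluate", log, {
      refMap <- buildReferenceMap(norm$spatial,
                                  labels = cellLabels(sp),
                                  vocabulary = typeVocabulary(pm))
      cm <- confusionMatrix(labels, cellLabels(sp))
      list(metrics = aggregateMetrics(pm, refMap),
           confusion = cm$matrix, accuracy = cm$accuracy)
    })
  }

  .stage("write", log, {
    writeProbabilityMatrix(pm, file.path(cfg$outDir, "probabilities.csv"))
    utils::write.csv(data.frame(obs_id = names(labels),
                                cell_type = unname(labels)),
                     file.path(cfg$outDir, "hard_labels.csv"),
                     row.names = FALSE, quote = FALSE)
    writeGenePanel(scores, file.path(cfg$outDir, "panel.txt"))
    writeGeneScoreTable(scores, file.path(cfg$outDir, "gene_scores.tsv"))
    saveClassifier(model, file.path(cfg$outDir, "model"))
    writeRunConfig(cfg, file.path(cfg$outDir, "resolved_config.yaml"))
    if (!is.null(report)) {
      utils::write.table(
        data.frame(metric = names(report$metrics),
                   value = unname(report$metrics)),
        file.path(cfg$outDir, "evaluation_metrics.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      utils::write.csv(report$confusion,
                       file.path(cfg$outDir, "confusion_matrix.csv"))
      log(sprintf("overall accuracy vs annotations: %.4f",
                  report$accuracy))
    }
    invisible(NULL)
  })
  writeLines(logLines, logPath)
  invisible(list(probabilities = pm, labels = labels, model = model,
                 scores = scores, report = report))
}

#' Write a simulated data pair to disk
#'
#' Convenience for the `simulate` CLI subcommand: writes the reference and
#' spatial data sets in mtx directory format plus ground-truth CSVs
#' (`truth_labels.csv`, `truth_proportions.csv`).
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(cfg, dir) {
  stopifnot(is(cfg, "SimulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulateReference(cfg)
  sim <- simulateSpatial(cfg)
  writeExpressionDataset(ref, file.path(dir, "reference"), "mtx")
  writeExpressionDataset(sim$dataset, file.path(dir, "spatial"), "mtx")
  utils::write.csv(data.frame(obs_id = names(sim$labels),
                              cell_type = unname(sim$labels)),
                   file.path(dir, "truth_labels.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(obs_id = rownames(sim$proportions),
                              sim$proportions, check.names = FALSE),
                   file.path(dir, "truth_proportions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
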