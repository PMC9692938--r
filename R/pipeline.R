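## End-to-end orchestration: pre-process -> extract -> select -> classify ->
## report. A single master seed deterministically derives every stage seed,
## so a rerun reproduces the identical selected indices and metrics.

#' Configuration for the end-to-end pipeline
#'
#' Stage seeds are derived from `seed` by a fixed rule
#' (`seed * 1000 + stage offset`), so no stage consumes global randomness
#' and reruns are identical.
#'
#' @param extractor `"autoencoder"`, `"raw_pixels"`, or
#'   `"cnn_adapter:<name>"` referencing a [registerBackbone()] entry
#' @param imageSize side length for the auto-encoder/raw-pixel path
#' @param hiddenDim auto-encoder code size
#' @param aeEpochs,aeLearningRate auto-encoder training parameters
#' @param aco an [acoConfig()]; its `subsetSize` must not exceed the
#'   extracted dimensionality (checked before any work)
#' @param classifier a [classifierSpec()] used for the final evaluation
#' @param trainFraction,splitRounding stratified split parameters (see
#'   [stratifiedSplit()])
#' @param seed master seed
#' @return a list of class `"PipelineConfig"`
#' @export
pipelineConfig <- function(extractor = "autoencoder", imageSize = 64L,
                           hiddenDim = 64L, aeEpochs = 150L,
                           aeLearningRate = 0.5,
                           aco = acoConfig(depositMode = "filter"),
                           classifier = classifierSpec("knn", k = 1L),
                           trainFraction = 0.8,
                           splitRounding = "floor_train", seed = 1L) {
  if (!inherits(aco, "ACOConfig")) stop("aco must come from acoConfig()")
  if (!inherits(classifier, "ClassifierSpec"))
    stop("classifier must come from classifierSpec()")
  known <- extractor %in% c("autoencoder", "raw_pixels") ||
    startsWith(extractor, "cnn_adapter:")
  if (!known) stop("unknown extractor: ", extractor)
  if (startsWith(extractor, "cnn_adapter:")) {
    bb <- sub("^cnn_adapter:", "", extractor)
    if (!bb %in% registeredBackbones())
      stop("backbone '", bb, "' is not registered")
  }
  structure(list(extractor = extractor, imageSize = as.integer(imageSize),
                 hiddenDim = as.integer(hiddenDim),
                 aeEpochs = as.integer(aeEpochs),
                 aeLearningRate = aeLearningRate, aco = aco,
                 classifier = classifier, trainFraction = trainFraction,
                 splitRounding = splitRounding, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.extract_stage <- function(records, trainIdx, testIdx, config) {
  if (startsWith(config$extractor, "cnn_adapter:")) {
    bb <- sub("^cnn_adapter:", "", config$extractor)
    full <- cnnFeatureAdapter(records, bb)
    return(list(train = subsetFeatures(full, samples = trainIdx),
                test = subsetFeatures(full, samples = testIdx),
                model = NULL))
  }
  pixels <- prepImages(records, size = config$imageSize)
  trainTab <- subsetFeatures(pixels, samples = trainIdx)
  testTab <- subsetFeatures(pixels, samples = testIdx)
  if (config$extractor == "raw_pixels")
    return(list(train = trainTab, test = testTab, model = NULL))
  aeCfg <- aeConfig(inputDim = nFeatures(pixels),
                    hiddenDim = config$hiddenDim,
                    epochs = config$aeEpochs,
                    learningRate = config$aeLearningRate,
                    seed = .stage_seed(config$seed, "autoencoder"))
  model <- trainAutoencoder(featureMatrix(trainTab), aeCfg)
  list(train = extractFeatures(featureMatrix(trainTab), model,
                               y = sampleLabels(trainTab)),
       test = extractFeatures(featureMatrix(testTab), model,
                              y = sampleLabels(testTab)),
       model = model)
}

#' Run the full pipeline on labeled image records
#'
#' Stages: stratified split, pre-processing (grayscale, resize, vectorize,
#' normalize), feature extraction (auto-encoder trained on the training
#' images only, raw pixels, or an external CNN adapter), ant colony feature
#' selection on the training table, and final train/test classification on
#' the selected subset.
#'
#' @param records list of [imageRecord()]s (e.g. from [loadImageDir()] or
#'   [makeImages()])
#' @param config a [pipelineConfig()]
#' @param outputDir optional directory; when given, the intermediate feature
#'   table, selection result and metric report are persisted there
#' @return list with `report` (\linkS4class{MetricReport}), `selection`
#'   (\linkS4class{SelectionResult}), `split`, `model` (the trained
#'   auto-encoder or `NULL`), `config`, `stageSeconds`
#' @export
runPipeline <- function(records, config = pipelineConfig(),
                        outputDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (length(records) == 0L) stop("no input records")
  took <- function(expr) system.time(expr)[["elapsed"]]
  timings <- c()

  split <- stratifiedSplit(records, config$trainFraction,
                           config$splitRounding,
                           seed = .stage_seed(config$seed, "split"))

  ext <- NULL
  timings["extract"] <- took(
    ext <- .extract_stage(records, split$train, split$test, config))

  acoCfg <- config$aco
  acoCfg$seed <- .stage_seed(config$seed, "aco")
  k <- .subset_size(acoCfg, nFeatures(ext$train))
  if (k > nFeatures(ext$train))
    stop("pre-flight check failed: subsetSize (", k,
         ") exceeds extracted dimensionality (", nFeatures(ext$train), ")")
  sel <- NULL
  timings["select"] <- took(sel <- runACO(ext$train, acoCfg))

  cls <- config$classifier
  cls$seed <- .stage_seed(config$seed, "classify")
  rep <- NULL
  timings["classify"] <- took(
    rep <- evaluateClassifier(cls,
                              subsetFeatures(ext$train, bestSubset(sel)),
                              subsetFeatures(ext$test, bestSubset(sel))))

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeFeatureTable(ext$train, file.path(outputDir, "features_train.csv"))
    writeFeatureTable(ext$test, file.path(outputDir, "features_test.csv"))
    writeSelectionResult(sel, file.path(outputDir, "selection.json"))
    writeMetricReport(rep, file.path(outputDir, "metrics.json"))
    writeSplitManifest(records, split, file.path(outputDir, "split.tsv"))
  }
  list(report = rep, selection = sel, split = split, model = ext$model,
       config = config, stageSeconds = timings)
}

#' Compare selection strategies on a shared split
#'
#' Evaluates three feature sets with the same classifier and the identical
#' train/test split: (a) all features, (b) the ant-colony-selected subset,
#' (c) a random subset of the same size. This mirrors the with/without-ACO
#' contrast used to justify selection.
#'
#' @param table a labeled \linkS4class{FeatureTable}
#' @param aco an [acoConfig()]
#' @param classifier a [classifierSpec()]
#' @param trainFraction,splitRounding,seed split parameters (master seed
#'   also drives the random baseline)
#' @return data.frame with one row per strategy: subset size, test accuracy,
#'   macro F1, macro MCC
#' @export
compareSelection <- function(table, aco = acoConfig(depositMode = "filter"),
                             classifier = classifierSpec("knn", k = 1L),
                             trainFraction = 0.8,
                             splitRounding = "floor_train", seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  if (is.null(sampleLabels(table))) stop("table must be labeled")
  split <- stratifiedSplit(sampleLabels(table), trainFraction,
                           splitRounding,
                           seed = .stage_seed(seed, "split"))
  trainTab <- subsetFeatures(table, samples = split$train)
  testTab <- subsetFeatures(table, samples = split$test)

  acoCfg <- aco
  acoCfg$seed <- .stage_seed(seed, "aco")
  sel <- runACO(trainTab, acoCfg)
  k <- length(bestSubset(sel))
  rnd <- randomSubsetBaseline(nFeatures(table), k,
                              seed = .stage_seed(seed, "synth"))
  sets <- list(all_features = seq_len(nFeatures(table)),
               aco_subset = bestSubset(sel),
               random_subset = rnd)
  rows <- lapply(names(sets), function(nm) {
    rep <- evaluateClassifier(classifier,
                              subsetFeatures(trainTab, sets[[nm]]),
                              subsetFeatures(testTab, sets[[nm]]))
    data.frame(strategy = nm, k = length(sets[[nm]]),
               acc = rep@overall[["acc"]], f1 = rep@overall[["f1"]],
               mcc = rep@overall[["mcc"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selection") <- sel
  out
}
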