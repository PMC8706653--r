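#' @include simulate.R evaluation.R signal_io.R
NULL

# ---- run configuration -----------------------------------------------------

#' Read a pipeline run configuration
#'
#' YAML (or JSON) file with optional sections `dataset`, `split`, `model`,
#' `train`, `cv` and top-level `seed` / `outputDir`; `overrides` (typically
#' parsed command-line flags) take precedence over file values, which take
#' precedence over package defaults. Exactly one dataset source must be
#' configured: `dataset$flatFile` (+ `windowLen`), `dataset$uciDir`
#' (+ `split`), or `dataset$simulate` (protocol fields).
#'
#' @param path config file path, or `NULL` for pure defaults/overrides.
#' @param overrides named list merged on top of the file values.
#' @return A validated list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list()
  else if (grepl("\\.json$", path)) read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- modifyList(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outputDir <- cfg$outputDir %||% "har_run"
  if (is.null(cfg$dataset)) cfg$dataset <- list(simulate = list())
  nSources <- sum(!vapply(cfg$dataset[c("flatFile", "uciDir", "simulate")],
                          is.null, TRUE))
  if (nSources != 1L)
    stop("config must name exactly one dataset source ",
         "(dataset$flatFile, dataset$uciDir or dataset$simulate)")
  structure(cfg, class = "RunConfig")
}

runConfigPart <- function(cfg, part, builder, allowed) {
  args <- cfg[[part]] %||% list()
  bad <- setdiff(names(args), allowed)
  if (length(bad))
    stop(sprintf("unknown %s config key(s): %s", part,
                 paste(bad, collapse = ", ")))
  do.call(builder, args)
}

loadConfiguredDataset <- function(cfg) {
  ds <- cfg$dataset
  if (!is.null(ds$flatFile))
    readFlatWindows(ds$flatFile, windowLen = ds$windowLen %||% 150L)
  else if (!is.null(ds$uciDir))
    readUciInertial(ds$uciDir, split = ds$split %||% "train")
  else {
    sim <- ds$simulate
    sim$seed <- sim$seed %||% cfg$seed
    generateDataset(do.call(protocolSpec, sim))
  }
}

writeManifest <- function(cfg, outDir, stage, extra = list()) {
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     config = unclass(cfg)), extra)
  write_json(manifest, file.path(outDir, paste0(stage, "_manifest.json")),
             auto_unbox = TRUE, digits = NA, null = "null")
}

# ---- pipeline stages -------------------------------------------------------

#' Pipeline stages
#'
#' Thin orchestration over the package API, also exposed through the
#' shipped command-line script (`system.file("cli", "har.R", package =
#' "harfusion")`). Every stage confines its outputs to the run's output
#' directory and writes a JSON manifest recording the configuration and
#' seed.
#'
#' \describe{
#'   \item{`runSimulate`}{writes the simulated windows as a device-dialect
#'     text file plus manifest.}
#'   \item{`runTrain`}{loads or simulates the dataset, splits it,
#'     normalizes on the training portion, trains the fusion model and
#'     writes checkpoint, history CSV and verification metrics.}
#'   \item{`runEvaluate`}{loads a checkpoint and evaluates a dataset,
#'     writing a metrics JSON and confusion CSV.}
#'   \item{`runCrossValidation`}{merged-data k-fold cross-validation with
#'     per-fold reports.}
#' }
#'
#' @param cfg a [readRunConfig()] result (or plain list with the same
#'   shape).
#' @param checkpoint for `runEvaluate`, path to a [saveModel()]
#'   checkpoint; defaults to the one `runTrain` wrote in `outputDir`.
#' @param verbose print progress.
#' @return Invisibly: the main artifact of the stage (see details).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(cfg, verbose = FALSE) {
  outDir <- cfg$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$dataset$simulate %||% list()
  sim$seed <- sim$seed %||% cfg$seed
  ws <- generateDataset(do.call(protocolSpec, sim))
  file <- file.path(outDir, "windows.txt")
  writeFlatWindows(ws, file)
  writeManifest(cfg, outDir, "simulate",
                list(nWindows = nWindows(ws),
                     classCounts = as.list(classCounts(ws)),
                     file = file))
  if (verbose) message(sprintf("wrote %d windows to %s", nWindows(ws), file))
  invisible(file)
}

#' @rdname pipeline
#' @export
runTrain <- function(cfg, verbose = FALSE) {
  outDir <- cfg$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ws <- loadConfiguredDataset(cfg)
  spec <- runConfigPart(cfg, "split", splitSpec,
                        c("trainFraction", "testFraction",
                          "verificationFraction", "stratified", "seed"))
  if (is.null((cfg$split %||% list())$seed)) spec$seed <- cfg$seed
  parts <- splitDataset(ws, spec)
  norm <- fitMinMax(parts$train)
  mArgs <- cfg$model %||% list()
  mArgs$windowLen <- mArgs$windowLen %||% windowLength(ws)
  modelCfg <- do.call(modelConfig, mArgs)
  tArgs <- cfg$train %||% list()
  tArgs$seed <- tArgs$seed %||% cfg$seed
  tCfg <- do.call(trainConfig, tArgs)
  model <- buildModel(modelCfg, seed = deriveSeed(cfg$seed, 7L))
  fit <- trainModel(model, normalizeWindows(parts$train, norm),
                    normalizeWindows(parts$verification, norm), tCfg,
                    verbose = verbose)
  ckpt <- file.path(outDir, "model.rds")
  saveModel(fit$model, ckpt)
  saveRDS(list(norm = norm, test = parts$test),
          file.path(outDir, "eval_inputs.rds"))
  write.table(fit$history, file.path(outDir, "history.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  pred <- predictActivities(fit$model, normalizeWindows(parts$test, norm))
  rep <- metricsReport(activityLabels(parts$test), pred,
                       nClasses = modelCfg@nClasses)
  writeMetrics(rep, file.path(outDir, "metrics"))
  writeManifest(cfg, outDir, "train",
                list(bestEpoch = attr(fit$history, "bestEpoch"),
                     epochs = nrow(fit$history),
                     testAccuracy = rep$accuracy, checkpoint = ckpt))
  if (verbose) message(sprintf("test accuracy %.2f%%", rep$accuracy))
  invisible(list(model = fit$model, history = fit$history, metrics = rep,
                 checkpoint = ckpt, norm = norm, parts = parts))
}

#' @rdname pipeline
#' @export
runEvaluate <- function(cfg, checkpoint = NULL, verbose = FALSE) {
  outDir <- cfg$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  checkpoint <- checkpoint %||% file.path(outDir, "model.rds")
  model <- loadModel(checkpoint)
  inputs <- file.path(outDir, "eval_inputs.rds")
  if (file.exists(inputs)) {
    ei <- readRDS(inputs)
    ws <- ei$test
    norm <- ei$norm
  } else {
    ws <- loadConfiguredDataset(cfg)
    norm <- fitMinMax(ws)                  # self-normalized fallback
  }
  pred <- predictActivities(model, normalizeWindows(ws, norm))
  rep <- metricsReport(activityLabels(ws), pred,
                       nClasses = model@config@nClasses)
  writeMetrics(rep, file.path(outDir, "metrics"))
  writeManifest(cfg, outDir, "evaluate",
                list(checkpoint = checkpoint, accuracy = rep$accuracy,
                     n = rep$n))
  if (verbose) message(sprintf("accuracy %.2f%% on %d windows",
                               rep$accuracy, rep$n))
  invisible(rep)
}

#' @rdname pipeline
#' @export
runCrossValidation <- function(cfg, verbose = FALSE) {
  outDir <- cfg$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ws <- loadConfiguredDataset(cfg)
  mArgs <- cfg$model %||% list()
  mArgs$windowLen <- mArgs$windowLen %||% windowLength(ws)
  modelCfg <- do.call(modelConfig, mArgs)
  tArgs <- cfg$train %||% list()
  tArgs$seed <- tArgs$seed %||% cfg$seed
  tCfg <- do.call(trainConfig, tArgs)
  cvArgs <- cfg$cv %||% list()
  cv <- kFoldCV(ws, modelCfg, tCfg, k = cvArgs$k %||% 10L,
                seed = cvArgs$seed %||% cfg$seed,
                stratified = cvArgs$stratified %||% TRUE, verbose = verbose)
  perFold <- data.frame(fold = seq_along(cv$accuracy),
                        accuracy = cv$accuracy)
  write.table(perFold, file.path(outDir, "cv_folds.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write_json(list(k = length(cv$accuracy), accuracy = cv$accuracy,
                  meanAccuracy = cv$meanAccuracy),
             file.path(outDir, "cv_metrics.json"), auto_unbox = TRUE,
             digits = NA)
  writeManifest(cfg, outDir, "cv", list(meanAccuracy = cv$meanAccuracy))
  if (verbose) message(sprintf("mean CV accuracy %.2f%%", cv$meanAccuracy))
  invisible(cv)
}

# Write a metrics report as JSON plus the confusion matrix as CSV.
writeMetrics <- function(rep, stem) {
  json <- rep
  json$confusion <- NULL
  write_json(json, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  write.table(confusionCounts(rep$confusion), paste0(stem, "_confusion.csv"),
              sep = ",", col.names = NA, quote = FALSE)
  invisible(stem)
}
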