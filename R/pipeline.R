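# End-to-end workflow: simulate -> preprocess -> build -> train -> predict
# -> evaluate, driven by a single configuration list that round-trips
# through YAML. Every stage writes its artifacts under the output
# directory; a run manifest records each emitted file with its md5 hash.
# The global seed propagates to every stochastic stage, so a config + seed
# reproduces a run exactly.

#' Default run configuration
#'
#' A complete, reduced-geometry demonstration configuration: 8 phantom
#' cases, a 3-level network and a short training schedule -- small enough
#' to run end-to-end on one CPU in a few minutes while exercising every
#' stage at full fidelity.
#'
#' @return nested list understood by \code{\link{runPipeline}}
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    phantom = list(n = 8L, mix = c(0.615, 0.34, 0.045),
                   gridShape = c(12L, 72L, 72L), spacingMM = c(3, 1, 1),
                   glandSemiaxesMM = c(14, 22, 24), noiseSigma = 0.05),
    preprocess = list(targetSpacingMM = c(3, 1, 1),
                      targetShape = c(16L, 64L, 64L), applyWGMask = TRUE),
    model = list(variant = "prolesa", levelWidths = c(8L, 16L, 32L),
                 reductionRatio = 8L, excitation = "relu"),
    train = list(loss = "dice_bce", learningRate = 1e-3, batchSize = 1L,
                 maxEpochs = 8L, patience = NA, targetDice = NA),
    logLevel = "info")
}

#' Read / write a run configuration
#'
#' YAML round-trip of the configuration list; unknown fields are rejected
#' early so typos fail before any compute.
#'
#' @param path YAML file
#' @return configuration list
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  mergeRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg configuration list (possibly partial; missing fields take
#'   defaults)
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

mergeRunConfig <- function(cfg) {
  def <- defaultRunConfig()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")))
  for (sec in names(cfg)) {
    if (is.list(def[[sec]])) {
      badf <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(badf))
        stop(sprintf("unknown field(s) in '%s': %s", sec,
                     paste(badf, collapse = ", ")))
      def[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else if (!is.null(cfg[[sec]])) def[[sec]] <- cfg[[sec]]
  }
  # validate the model section before any compute
  if (!def$model$variant %in% modelVariants())
    stop(sprintf("unknown variant '%s' (choose from: %s)", def$model$variant,
                 paste(modelVariants(), collapse = ", ")))
  def
}

logMsg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

manifestAdd <- function(manifest, stage, paths) {
  rbind(manifest,
        data.frame(stage = stage, file = paths,
                   md5 = unname(tools::md5sum(paths)),
                   stringsAsFactors = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, build, train, predict and evaluate in
#' order, writing artifacts under \code{outDir}: phantom NIfTI volumes and
#' cohort manifest, a model checkpoint, training log CSV, predicted masks,
#' the per-case metrics CSV and the stratified report (CSV and JSON), plus
#' a run manifest with an md5 hash per emitted file and the effective
#' configuration. Stages whose outputs already exist are reused when
#' \code{resume = TRUE}; a stage finding its upstream artifacts missing
#' stops with the absent file named.
#'
#' @param cfg configuration list (see \code{\link{defaultRunConfig}}) or a
#'   YAML path
#' @param outDir output directory
#' @param stages subset of \code{c("simulate", "preprocess", "train",
#'   "predict", "evaluate")} to run (earlier stages must have run before)
#' @param resume reuse existing artifacts instead of recomputing
#' @return the stratified report data.frame (when evaluate runs),
#'   invisibly otherwise
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outDir,
                        stages = c("simulate", "preprocess", "train",
                                   "predict", "evaluate"),
                        resume = FALSE) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  else cfg <- mergeRunConfig(cfg)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeRunConfig(cfg, file.path(outDir, "config.yaml"))
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  seed <- as.integer(cfg$seed)
  caseDir <- file.path(outDir, "cases")
  predDir <- file.path(outDir, "predictions")
  manPath <- file.path(caseDir, "manifest.csv")

  if ("simulate" %in% stages && !(resume && file.exists(manPath))) {
    logMsg("info", "simulate: %d phantom cases", cfg$phantom$n)
    generateCohort(cfg$phantom$n, unlist(cfg$phantom$mix), seed = seed,
                   outDir = caseDir,
                   gridShape = unlist(cfg$phantom$gridShape),
                   spacingMM = unlist(cfg$phantom$spacingMM),
                   glandSemiaxesMM = unlist(cfg$phantom$glandSemiaxesMM),
                   noiseSigma = cfg$phantom$noiseSigma)
    manifest <- manifestAdd(manifest, "simulate",
                            list.files(caseDir, full.names = TRUE))
  }
  if (!file.exists(manPath))
    stop(sprintf("missing upstream artifact: %s (run the simulate stage)",
                 manPath))
  cohortMan <- utils::read.csv(manPath, stringsAsFactors = FALSE)

  ppc <- PreprocessConfig(unlist(cfg$preprocess$targetSpacingMM),
                          unlist(cfg$preprocess$targetShape),
                          cfg$preprocess$applyWGMask)
  loadInputs <- function() {
    lapply(cohortMan$id, function(id)
      preprocessCase(readCase(id, caseDir), ppc))
  }

  ckptPath <- file.path(outDir, "model.ckpt.gz")
  logPath <- file.path(outDir, "training_log.csv")
  if ("train" %in% stages && !(resume && file.exists(ckptPath))) {
    logMsg("info", "preprocess + train: variant %s", cfg$model$variant)
    inputs <- loadInputs()
    mcfg <- ModelConfig(cfg$model$variant,
                        inputShape = unlist(cfg$preprocess$targetShape),
                        levelWidths = unlist(cfg$model$levelWidths),
                        reductionRatio = cfg$model$reductionRatio,
                        excitation = cfg$model$excitation,
                        seed = seed)
    model <- buildModel(mcfg)
    tcfg <- TrainConfig(loss = cfg$train$loss,
                        learningRate = cfg$train$learningRate,
                        batchSize = cfg$train$batchSize,
                        maxEpochs = cfg$train$maxEpochs,
                        patience = if (is.null(cfg$train$patience) ||
                                       is.na(cfg$train$patience)) NA_integer_
                                   else as.integer(cfg$train$patience),
                        targetDice = if (is.null(cfg$train$targetDice) ||
                                         is.na(cfg$train$targetDice)) NA_real_
                                     else as.numeric(cfg$train$targetDice),
                        seed = seed)
    res <- trainModel(model, inputs, tcfg)
    saveCheckpoint(fittedModel(res), ckptPath)
    utils::write.csv(trainHistory(res), logPath, row.names = FALSE)
    manifest <- manifestAdd(manifest, "train", c(ckptPath, logPath))
  }

  if ("predict" %in% stages || "evaluate" %in% stages) {
    if (!file.exists(ckptPath))
      stop(sprintf("missing upstream artifact: %s (run the train stage)",
                   ckptPath))
  }
  if ("predict" %in% stages && !(resume && dir.exists(predDir))) {
    logMsg("info", "predict: %d cases", nrow(cohortMan))
    model <- loadCheckpoint(ckptPath)
    dir.create(predDir, recursive = TRUE, showWarnings = FALSE)
    inputs <- loadInputs()
    for (mi in inputs) {
      pm <- predictCase(model, mi)
      writeVolume(pm, file.path(predDir, paste0(mi@id, "_pred.nii.gz")))
    }
    manifest <- manifestAdd(manifest, "predict",
                            list.files(predDir, full.names = TRUE))
  }

  report <- NULL
  if ("evaluate" %in% stages) {
    logMsg("info", "evaluate")
    inputs <- loadInputs()
    rows <- lapply(inputs, function(mi) {
      pp <- file.path(predDir, paste0(mi@id, "_pred.nii.gz"))
      if (!file.exists(pp))
        stop(sprintf("missing upstream artifact: %s (run the predict stage)",
                     pp))
      pred <- readVolume(pp, mask = TRUE)
      caseMetrics(mi@label, pred@values, spacing = mi@spacing, id = mi@id)
    })
    percase <- do.call(rbind, rows)
    report <- aggregateMetrics(percase)
    pc <- file.path(outDir, "per_case_metrics.csv")
    rc <- file.path(outDir, "stratified_report.csv")
    rj <- file.path(outDir, "stratified_report.json")
    utils::write.csv(percase, pc, row.names = FALSE)
    utils::write.csv(report, rc, row.names = FALSE)
    jsonlite::write_json(report, rj, dataframe = "rows", na = "string",
                         auto_unbox = TRUE, digits = NA)
    manifest <- manifestAdd(manifest, "evaluate", c(pc, rc, rj))
  }
  utils::write.csv(manifest, file.path(outDir, "run_manifest.csv"),
                   row.names = FALSE)
  if (is.null(report)) invisible(NULL) else report
}
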