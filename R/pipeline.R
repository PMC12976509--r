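#' Default run configuration
#'
#' Nested configuration of the full workflow (simulate, patch, train,
#' score, evaluate). The `"desk"` profile is sized for a single CPU core:
#' 512-px synthetic fields, 10 training epochs, batch 32, 64-px network
#' input. The `"paper"` profile carries the original recipe's settings
#' (112-px patches at stride 100, 4-patch sampling over 100 Monte-Carlo
#' rounds, 200 epochs, batch 128, learning rate 1e-4, 224-px input).
#'
#' @param profile `"desk"` or `"paper"`.
#' @return Nested named list of class `"RunConfig"`.
#' @export
defaultRunConfig <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    seed = 1,
    out = "mitoscore_run",
    simulate = list(nFieldsPerClass = 30, fieldSizePx = 512,
                    nExperiments = 6, noiseLevel = 0.05),
    patch = list(patchSize = 112, stride = 100, minFg = 0.5),
    train = list(task = "CCCP-FL3-NC", epochs = 10, lr = 1e-4,
                 batchSize = 32, inputSize = 64, baseWidth = 8),
    score = list(rounds = 100, k = 4),
    evaluate = list(nFolds = 5, testFolds = 0))
  if (profile == "paper") {
    cfg$train$epochs <- 200
    cfg$train$batchSize <- 128
    cfg$train$inputSize <- 224
    cfg$evaluate$testFolds <- NULL   # full cross-validation
  }
  structure(cfg, class = "RunConfig")
}

# Recursive merge with strict key validation: unknown keys are a
# configuration error naming the offending key.
.mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("validation error: unknown config key '%s'", full))
    if (is.list(defaults[[key]]) && is.list(user[[key]]))
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' @param config A YAML file path, a (partial) named list layered over
#'   [defaultRunConfig()], or `NULL` for pure defaults.
#' @param profile Base profile when `config` does not set one.
#' @return Validated `"RunConfig"` list.
#' @export
loadRunConfig <- function(config = NULL, profile = "desk") {
  user <- if (is.null(config)) list()
    else if (is.character(config)) yaml::read_yaml(config)
    else config
  if (!is.null(user$profile)) profile <- user$profile
  cfg <- .mergeConfig(unclass(defaultRunConfig(profile)), user)
  structure(cfg, class = "RunConfig")
}

.configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

.stageCached <- function(dir, hash) {
  hf <- file.path(dir, ".config_hash")
  file.exists(hf) && identical(readLines(hf, warn = FALSE)[1], hash)
}

.markStage <- function(dir, hash) {
  writeLines(hash, file.path(dir, ".config_hash"))
}

#' Run the full pipeline
#'
#' Executes simulate, fold assignment, train, score and evaluate in order,
#' caching each stage by a hash of its configuration section (re-running
#' with an identical config is a no-op on cached stages). Every output is
#' traceable through the run manifest (`run.json`), which records the
#' config snapshot, the root seed, and per-stage artifact lists.
#'
#' @param config See [loadRunConfig()].
#' @param quiet Suppress progress messages.
#' @return The run directory path, invisibly.
#' @export
runPipeline <- function(config = NULL, quiet = FALSE) {
  cfg <- loadRunConfig(config)
  runDir <- cfg$out
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(runDir, "run.log")
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logFile, append = TRUE)
    if (!quiet) message(line)
  }
  writeLines(yaml::as.yaml(unclass(cfg)), file.path(runDir, "config.yaml"))
  artifacts <- list()

  # stage 1: simulate -------------------------------------------------------
  simDir <- file.path(runDir, "data")
  simHash <- .configHash(list(cfg$simulate, cfg$seed))
  if (.stageCached(simDir, simHash)) {
    say("simulate: cached, skipping")
  } else {
    say("simulate: %d fields/class at %d px", cfg$simulate$nFieldsPerClass,
        cfg$simulate$fieldSizePx)
    specs <- defaultClassSpecs(fieldSizePx = cfg$simulate$fieldSizePx,
                               noiseLevel = cfg$simulate$noiseLevel)
    generateDataset(specs, cfg$simulate$nFieldsPerClass, simDir,
                    seed = cfg$seed,
                    nExperiments = cfg$simulate$nExperiments)
    .markStage(simDir, simHash)
  }
  manifest <- readManifest(file.path(simDir, "manifest.csv"))
  artifacts$manifest <- file.path(simDir, "manifest.csv")

  # stage 2: folds ----------------------------------------------------------
  folds <- makeGroupedFolds(manifest, nFolds = cfg$evaluate$nFolds,
                            seed = deriveSeed(cfg$seed, 2L))
  foldsPath <- file.path(runDir, "folds.csv")
  write.csv(folds@assignment, foldsPath, row.names = FALSE)
  write.csv(folds@counts, file.path(runDir, "fold_counts.csv"),
            row.names = FALSE)
  artifacts$folds <- foldsPath

  # stage 3-5: train + score + evaluate -------------------------------------
  evalDir <- file.path(runDir, "evaluation")
  evalHash <- .configHash(list(cfg$patch, cfg$train, cfg$score,
                               cfg$evaluate, cfg$seed))
  if (.stageCached(evalDir, evalHash)) {
    say("evaluate: cached, skipping")
  } else {
    dir.create(evalDir, showWarnings = FALSE, recursive = TRUE)
    tcfg <- trainConfig(task = cfg$train$task, epochs = cfg$train$epochs,
                        lr = cfg$train$lr, batchSize = cfg$train$batchSize,
                        inputSize = cfg$train$inputSize,
                        baseWidth = cfg$train$baseWidth,
                        seed = deriveSeed(cfg$seed, 3L))
    testFolds <- cfg$evaluate$testFolds
    say("train/score task %s on folds [%s]", cfg$train$task,
        if (is.null(testFolds)) "all" else paste(testFolds, collapse = ","))
    cv <- crossValidate(manifest, folds, tcfg, testFolds = testFolds,
                        rounds = cfg$score$rounds, k = cfg$score$k,
                        patchSize = cfg$patch$patchSize,
                        stride = cfg$patch$stride, minFg = cfg$patch$minFg,
                        seed = deriveSeed(cfg$seed, 4L))
    write.csv(cv$fieldScores, file.path(evalDir, "scores.csv"),
              row.names = FALSE)
    write.csv(cv$metrics, file.path(evalDir, "metrics.csv"),
              row.names = FALSE)
    write.csv(cv$foldScoreTable, file.path(evalDir, "fold_scores.csv"),
              row.names = FALSE)
    for (f in names(cv$models))
      saveModel(cv$models[[f]], file.path(evalDir, paste0("model_fold", f)))
    .markStage(evalDir, evalHash)
    say("evaluate: wrote scores.csv, metrics.csv, fold_scores.csv")
  }
  artifacts$evaluation <- evalDir

  runManifest <- list(
    config = unclass(cfg), seed = cfg$seed,
    config_hash = .configHash(unclass(cfg)),
    artifacts = artifacts,
    files = as.list(tools::md5sum(list.files(runDir, recursive = TRUE,
                                             full.names = TRUE,
                                             pattern = "\\.(csv|yaml)$"))))
  jsonlite::write_json(runManifest, file.path(runDir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  say("run complete: %s", runDir)
  invisible(runDir)
}
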