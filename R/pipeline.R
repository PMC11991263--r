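#' Save / load model weights
#'
#' Serializes every unique parameter tensor of a model (weights, biases,
#' normalization statistics) to an RDS file. `loadModelWeights` restores
#' them into a model built with the same configuration and seed
#' structure.
#'
#' @param model a `libsModel`.
#' @param path file path.
#' @return invisibly, `path` / the model.
#' @export
saveModelWeights <- function(model, path) {
  ps <- .unique_params(model)
  payload <- lapply(ps, function(p) {
    vals <- lapply(p$pnames, function(nm) get(nm, p))
    names(vals) <- p$pnames
    if (identical(p$kind, "bn")) {
      vals$running_mean <- p$running_mean
      vals$running_var <- p$running_var
      vals$running_mean2 <- p$running_mean2
      vals$running_var2 <- p$running_var2
    }
    vals
  })
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveModelWeights
#' @export
loadModelWeights <- function(model, path) {
  payload <- readRDS(path)
  ps <- .unique_params(model)
  if (length(payload) != length(ps))
    stop("loadModelWeights: weight file does not match the model structure",
         call. = FALSE)
  for (i in seq_along(ps)) {
    p <- ps[[i]]
    for (nm in p$pnames) assign(nm, payload[[i]][[nm]], p)
    if (identical(p$kind, "bn")) {
      p$running_mean <- payload[[i]]$running_mean
      p$running_var <- payload[[i]]$running_var
      p$running_mean2 <- payload[[i]]$running_mean2 %||% p$running_mean
      p$running_var2 <- payload[[i]]$running_var2 %||% p$running_var
    }
  }
  invisible(model)
}

.read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) config
  else stop("runPipeline: config must be a file path or a list",
            call. = FALSE)
}

.synth_from_config <- function(sc, seed) {
  if (!is.null(sc$path))
    return(readSpectra(sc$path, sc$manifest))
  preset <- sc$preset %||% "default"
  cfg <- switch(preset,
    default = defaultSynthConfig(seed = sc$seed %||% seed),
    single_line = singleLineConfig(seed = sc$seed %||% seed),
    stop(sprintf("unknown synth preset '%s'", preset), call. = FALSE))
  for (f in c("tabletsPerClass", "shotsPerTablet", "noiseSd",
              "tabletJitterSd", "nPoints"))
    if (!is.null(sc[[f]])) slot(cfg, f) <-
      if (f %in% c("tabletsPerClass", "shotsPerTablet", "nPoints"))
        as.integer(sc[[f]]) else as.numeric(sc[[f]])
  validObject(cfg)
  generateSpectra(cfg)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates generate (or load) - preprocess - split - train -
#' evaluate - compare - explain under one configuration, writing a
#' self-describing run directory: config snapshot, a timestamped stage
#' log, per-epoch metrics, confusion matrices, comparison table,
#' saliency maps, and serialized weights. Rerunning with the same config
#' and seed reproduces all artifacts.
#'
#' @param config a nested list or a path to a YAML/JSON file with
#'   optional sections `synth` (either `path`/`manifest` pointing at
#'   spectra on disk or `preset` = `"default"`/`"single_line"` plus
#'   overrides), `preprocess` ([preprocessConfig()] arguments), `model`
#'   ([netConfig()] arguments), `train` ([trainConfig()] arguments),
#'   `comparisons` (character vector of `knn`/`rf`/`dt`/`lenet`/
#'   `alexnet_mod`/`resnet18`), `gradcam` (`n` spectra to explain), and
#'   `seed`.
#' @param outputDir run directory (created if missing); overrides
#'   `config$output_dir`.
#' @return invisibly, the run manifest (named list of artifact paths and
#'   headline metrics).
#' @export
runPipeline <- function(config, outputDir = NULL) {
  cfg <- .read_run_config(config)
  outDir <- outputDir %||% cfg$output_dir %||%
    stop("runPipeline: no output directory configured", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  logFile <- file.path(outDir, "run.log")
  logmsg <- function(stage, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, sprintf(...))
    cat(line, "\n", file = logFile, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    logmsg(name, "start")
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    logmsg(name, "done")
    r
  }
  manifest <- list(output_dir = outDir)
  yaml::write_yaml(cfg, file.path(outDir, "config_snapshot.yaml"))
  manifest$config_snapshot <- file.path(outDir, "config_snapshot.yaml")

  ds <- stage("generate", .synth_from_config(cfg$synth %||% list(), seed))
  pp <- stage("preprocess", {
    pcfg <- do.call(preprocessConfig, cfg$preprocess %||% list())
    preprocessSpectra(ds, pcfg)
  })

  tArgs <- cfg$train %||% list()
  if (is.null(tArgs$seed)) tArgs$seed <- seed
  tcfg <- do.call(trainConfig, tArgs)
  mcfg <- do.call(netConfig, c(list(inputLength = nrow(pp),
                                    nClasses = length(spectrumClasses(pp))),
                               cfg$model %||% list()))
  parts <- stage("split",
    splitDataset(pp, tcfg@splitRatios, seed = tcfg@seed,
                 groupAware = tcfg@groupAwareSplit))

  model <- buildModel(mcfg, seed = tcfg@seed)
  tr <- stage("train", trainModel(model, parts$train, parts$val, tcfg))
  data.table::fwrite(tr$traces, file.path(outDir, "metrics.csv"))
  manifest$metrics <- file.path(outDir, "metrics.csv")
  saveModelWeights(model, file.path(outDir, "weights.rds"))
  manifest$weights <- file.path(outDir, "weights.rds")

  ev <- stage("evaluate",
    evaluateModel(model, parts$test %||% parts$val, tr$traces))
  utils::write.csv(confusionCounts(ev),
                   file.path(outDir, "confusion_test.csv"))
  manifest$confusion <- file.path(outDir, "confusion_test.csv")
  manifest$test_accuracy <- accuracy(ev)
  logmsg("evaluate", "test accuracy %.4f", accuracy(ev))

  comps <- cfg$comparisons %||% character()
  if (length(comps)) {
    tab <- stage("compare",
      compareMethods(pp, methods = comps, seed = seed,
                     cnnEpochs = as.integer(cfg$comparison_epochs %||% 3L),
                     cnnLearningRate =
                       as.numeric(cfg$comparison_lr %||% 0.01)))
    data.table::fwrite(tab, file.path(outDir, "comparison.csv"))
    manifest$comparison <- file.path(outDir, "comparison.csv")
  }

  nCam <- as.integer((cfg$gradcam %||% list())$n %||% 1L)
  if (nCam > 0L) {
    stage("explain", {
      test <- parts$test %||% parts$val
      for (i in seq_len(min(nCam, ncol(test)))) {
        sm <- gradCam1d(model, test[, i])
        writeSaliency(sm, file.path(outDir, sprintf("saliency_%03d.csv", i)))
      }
    })
    manifest$saliency <- file.path(outDir, "saliency_001.csv")
  }
  yaml::write_yaml(
    c(manifest[!vapply(manifest, is.numeric, TRUE)],
      list(test_accuracy = manifest$test_accuracy)),
    file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

#' Run all comparison methods on one dataset
#'
#' Applies any subset of the comparison suite to a dataset: classical ML
#' classifiers under the 7:3 + five-fold-CV protocol, and classic 1-D
#' CNNs under the 6:2:2 protocol, producing one results table.
#'
#' @param ds a (preprocessed) [SpectralSet-class].
#' @param methods subset of `knn`, `rf`, `dt`, `lenet`, `alexnet_mod`,
#'   `resnet18`.
#' @param seed seed for splits and training.
#' @param cnnEpochs,cnnLearningRate,cnnBatchSize training budget for the
#'   CNN baselines.
#' @return `data.frame` with `method`, `accuracy_pct` (held-out split)
#'   and `cv_accuracy_pct` (ML methods only).
#' @export
compareMethods <- function(ds, methods = c("knn", "rf", "dt"), seed = 0L,
                           cnnEpochs = 3L, cnnLearningRate = 0.01,
                           cnnBatchSize = 32L) {
  mlNames <- c("knn", "rf", "dt")
  cnnNames <- c("lenet", "alexnet_mod", "resnet18")
  bad <- setdiff(methods, c(mlNames, cnnNames))
  if (length(bad))
    stop(sprintf("compareMethods: unknown methods: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  rows <- list()
  for (m in intersect(methods, mlNames)) {
    r <- runMl(ds, mlSpec(m), seed = seed)
    rows[[m]] <- data.frame(method = m,
                            accuracy_pct = round(100 * accuracy(r$eval), 1),
                            cv_accuracy_pct = round(100 * r$cv_accuracy, 1))
  }
  cnns <- intersect(methods, cnnNames)
  if (length(cnns)) {
    parts <- splitDataset(ds, c(0.6, 0.2, 0.2), seed = seed)
    tcfg <- trainConfig(learningRate = cnnLearningRate, epochs = cnnEpochs,
                        batchSize = cnnBatchSize, seed = seed)
    for (m in cnns) {
      mod <- buildClassicCnn(m, inputLength = nrow(ds),
                             nClasses = length(spectrumClasses(ds)),
                             seed = seed)
      trainModel(mod, parts$train, parts$val, tcfg)
      ev <- evaluateModel(mod, parts$test)
      rows[[m]] <- data.frame(method = m,
                              accuracy_pct = round(100 * accuracy(ev), 1),
                              cv_accuracy_pct = NA_real_)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
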