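# Config-driven experiment orchestration: simulate -> train -> evaluate ->
# analyze, with provenance (config hash, seeds) in every artifact.

#' Build an experiment configuration
#'
#' The configuration is a plain serialisable list (YAML round-trippable);
#' every artifact written by \code{\link{runExperiment}} records its hash.
#'
#' @param imageSize phantom / reconstruction side in pixels.
#' @param nTrain,nTest dataset sizes.
#' @param family training phantom family.
#' @param textureSigma intra-body texture sd of the training family.
#' @param geometries character vector of protocol presets to simulate.
#' @param beam beam type.
#' @param noiseLevel sinogram noise level.
#' @param filterWindow,filterCutoff FBP filter settings.
#' @param network \code{"3l-ssnet"} or \code{"resunet"}.
#' @param variant 3L-SSNet variant.
#' @param c0 ResUNet base width.
#' @param optimizer,epochs,batchSize training settings (optimizer defaults to
#'   the network's preset).
#' @param scenarios character vector of OOD scenario kinds to run (may be
#'   empty).
#' @param outDir artifact directory.
#' @param seed global seed.
#' @return a list of class \code{greenct_config}.
#' @export
experimentConfig <- function(imageSize = 128L, nTrain = 200L, nTest = 20L,
                             family = "chest", textureSigma = 0.02,
                             geometries = c("full-range", "half-range"),
                             beam = "fan-flat", noiseLevel = 1e-2,
                             filterWindow = "ram-lak", filterCutoff = 1,
                             network = "3l-ssnet",
                             variant = "table-consistent", c0 = 16L,
                             optimizer = NULL, epochs = 15L, batchSize = 8L,
                             scenarios = character(0), outDir = tempfile(),
                             seed = 1L) {
  if (is.null(optimizer))
    optimizer <- if (network == "3l-ssnet") "adam" else "sgd-nesterov"
  scenarios <- as.character(unlist(scenarios))
  cfg <- list(imageSize = as.integer(imageSize), nTrain = as.integer(nTrain),
              nTest = as.integer(nTest), family = family,
              textureSigma = textureSigma, geometries = geometries,
              beam = beam, noiseLevel = noiseLevel,
              filterWindow = filterWindow, filterCutoff = filterCutoff,
              network = network, variant = variant, c0 = as.integer(c0),
              optimizer = optimizer, epochs = as.integer(epochs),
              batchSize = as.integer(batchSize), scenarios = scenarios,
              outDir = outDir, seed = as.integer(seed))
  class(cfg) <- "greenct_config"
  cfg
}

#' @rdname experimentConfig
#' @param outDir,seed see above.
#' @export
smokeExperimentConfig <- function(outDir = tempfile(), seed = 1L) {
  experimentConfig(imageSize = 64L, nTrain = 20L, nTest = 4L,
                   geometries = "full-range", epochs = 3L,
                   scenarios = character(0), outDir = outDir, seed = seed)
}

#' Read / write an experiment configuration as YAML
#'
#' @param cfg a config from \code{\link{experimentConfig}}.
#' @param path YAML file path.
#' @return \code{readExperimentConfig} returns the config list.
#' @export
writeExperimentConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experimentConfig, cfg[setdiff(names(cfg), character(0))])
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialisation; recorded in every artifact so
#' outputs can be traced to the exact settings that produced them.
#'
#' @param cfg a config list.
#' @return character hash.
#' @export
configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

buildNetworkFromConfig <- function(cfg) {
  if (cfg$network == "3l-ssnet") build3LSSNet(cfg$variant, seed = cfg$seed)
  else buildResUNet(c0 = cfg$c0, seed = cfg$seed)
}

#' Run a full experiment from a configuration
#'
#' Pipeline: generate phantoms; simulate sinograms and FBP reconstructions
#' under every configured protocol; train the configured network on the
#' merged training pairs; evaluate FBP and the network per protocol; run the
#' configured OOD scenarios; emit the cost / receptive-field analysis.  All
#' artifacts (TIFF images, TSV sinograms, CSV/JSON metrics, RDS checkpoint,
#' JSON manifest) land in \code{cfg$outDir}.  A finished stage leaves its
#' outputs on disk, so a rerun with \code{resume = TRUE} skips completed
#' stages.
#'
#' @param cfg configuration from \code{\link{experimentConfig}}.
#' @param resume skip stages whose outputs already exist.
#' @param verbose print stage progress.
#' @return invisibly, the artifact directory path.
#' @export
runExperiment <- function(cfg, resume = FALSE, verbose = FALSE) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  writeExperimentConfig(cfg, file.path(cfg$outDir, "config.yaml"))
  filt <- filterSpec(cfg$filterWindow, cfg$filterCutoff)

  say("stage 1/5: phantoms")
  trainGts <- generateDataset(cfg$nTrain,
                              phantomSpec(cfg$family, cfg$imageSize,
                                          textureSigma = cfg$textureSigma),
                              seed = deriveSeed(cfg$seed, 11L))
  testGts <- generateDataset(cfg$nTest,
                             phantomSpec(cfg$family, cfg$imageSize,
                                         textureSigma = cfg$textureSigma),
                             seed = deriveSeed(cfg$seed, 12L))
  phDir <- file.path(cfg$outDir, "phantoms")
  dir.create(phDir, showWarnings = FALSE)
  for (i in seq_along(testGts))
    writeImageTIFF(testGts[[i]], file.path(phDir, sprintf("test_%03d.tiff", i)))

  say("stage 2/5: simulation + FBP")
  trainSets <- list(); testSets <- list()
  snDir <- file.path(cfg$outDir, "sinograms")
  rcDir <- file.path(cfg$outDir, "reconstructions")
  dir.create(snDir, showWarnings = FALSE)
  dir.create(rcDir, showWarnings = FALSE)
  for (g in cfg$geometries) {
    geom <- makeGeometry(g, cfg$imageSize, beam = cfg$beam)
    trainSets[[g]] <- buildPairs(trainGts, geom, cfg$noiseLevel, filt,
                                 seed = deriveSeed(cfg$seed, 21L), "train")
    testSets[[g]] <- buildPairs(testGts, geom, cfg$noiseLevel, filt,
                                seed = deriveSeed(cfg$seed, 22L), "test")
    sino <- addNoise(forwardProject(testGts[[1]], geom), cfg$noiseLevel,
                     deriveSeed(cfg$seed, 23L))
    writeSinogramTSV(sino, file.path(snDir, paste0(g, "_test001.tsv")))
    rcPath <- file.path(rcDir, paste0(g, "_fbp_test001.tiff"))
    writeImageTIFF(scaleToUnit(testSets[[g]]@y[[1]]), rcPath)
    jsonlite::write_json(
      list(geometry = geometryToList(geom),
           filter = list(window = cfg$filterWindow,
                         cutoff = cfg$filterCutoff),
           noiseLevel = cfg$noiseLevel, seed = deriveSeed(cfg$seed, 22L),
           configHash = hash),
      paste0(rcPath, ".json"), auto_unbox = TRUE, digits = NA)
  }
  trainData <- if (length(trainSets) == 1) trainSets[[1]]
  else do.call(mergePairs, unname(trainSets))

  say("stage 3/5: training (%s)", cfg$network)
  ckpt <- file.path(cfg$outDir, "checkpoint.rds")
  if (resume && file.exists(ckpt)) {
    net <- readNetwork(ckpt)
    history <- NULL
  } else {
    net0 <- buildNetworkFromConfig(cfg)
    tc <- trainConfig(cfg$optimizer, epochs = cfg$epochs,
                      batchSize = cfg$batchSize,
                      seed = deriveSeed(cfg$seed, 31L))
    fit <- trainNetwork(net0, trainData, tc)
    net <- fit$network
    history <- fit$history
    writeNetwork(net, ckpt)
    jsonlite::write_json(
      list(configHash = hash, seed = cfg$seed, optimizer = cfg$optimizer,
           epochs = cfg$epochs,
           loss = history$loss, lr = history$lr),
      file.path(cfg$outDir, "training_log.json"),
      auto_unbox = TRUE, digits = NA)
  }

  say("stage 4/5: evaluation")
  mtDir <- file.path(cfg$outDir, "metrics")
  dir.create(mtDir, showWarnings = FALSE)
  for (g in cfg$geometries) {
    repFBP <- evaluateMethod(NULL, testSets[[g]])
    repNet <- evaluateMethod(net, testSets[[g]])
    tab <- metricsTable(repFBP, repNet)
    write.csv(tab, file.path(mtDir, paste0(g, "_summary.csv")),
              row.names = FALSE)
    per <- rbind(cbind(method = repFBP@method, metricTable(repFBP)),
                 cbind(method = repNet@method, metricTable(repNet)))
    write.csv(per, file.path(mtDir, paste0(g, "_per_image.csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(configHash = hash, geometry = g,
           fbp = as.list(metricMeans(repFBP)),
           network = as.list(metricMeans(repNet))),
      file.path(mtDir, paste0(g, "_summary.json")),
      auto_unbox = TRUE, digits = NA)
  }

  if (length(cfg$scenarios)) {
    say("stage 4b: out-of-domain scenarios")
    for (sc in cfg$scenarios) {
      res <- runOOD(net, oodScenario(sc, cfg$geometries[1]),
                    imageSize = cfg$imageSize, nImages = cfg$nTest,
                    seed = deriveSeed(cfg$seed, 41L), beam = cfg$beam,
                    trainNoise = cfg$noiseLevel, filt = filt,
                    indomain = testSets[[cfg$geometries[1]]])
      jsonlite::write_json(
        list(configHash = hash, kind = sc,
             ood = as.list(metricMeans(res$oodModel)),
             oodFBP = as.list(metricMeans(res$oodFBP)),
             indomain = as.list(metricMeans(res$indomainModel)),
             indomainFBP = as.list(metricMeans(res$indomainFBP)),
             deltas = as.list(res$deltas)),
        file.path(mtDir, paste0("ood_", sc, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }

  say("stage 5/5: architecture analysis")
  analyzeNetwork(net, inputSide = cfg$imageSize,
                 path = file.path(cfg$outDir, "analysis.json"))
  jsonlite::write_json(
    list(configHash = hash, seed = cfg$seed,
         package = as.character(utils::packageVersion("greenCT")),
         geometries = cfg$geometries, network = cfg$network,
         artifacts = list.files(cfg$outDir, recursive = TRUE)),
    file.path(cfg$outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(cfg$outDir)
}
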