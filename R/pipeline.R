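#' Default pipeline configuration
#'
#' All tunables of [runPipeline()] with their defaults. User configs
#' (YAML or list) are merged over these, and the fully resolved
#' configuration is printed into the run report so omitted keys stay
#' auditable.
#'
#' @return a nested list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    outDir = "flimox-run",
    stages = c("simulate", "fit", "calibrate", "po2map", "summarize"),
    scene = list(
      imageHeight = 64L, imageWidth = 64L, nChannels = 256L,
      timeWindow = 12.5, mitoCount = 10L, mitoRadiusRange = c(2, 5),
      backgroundPhotonRate = 10, mitoPhotonBudget = 5000,
      truthK = 15, truthTauMax = 2.5, tauFloor = 0.914,
      shortLifetime = 0.45, shortFraction = 0.25),
    conditions = list(
      WT = list(weights = c(0.6, 0.4), means = c(10, 60), sds = c(3, 10),
                nImages = 20L),
      KO = list(weights = c(0.2, 0.8), means = c(10, 60), sds = c(3, 10),
                nImages = 20L)),
    calibration = list(levels = c(0, 5, 10, 20, 40, 80, 120, 160)),
    fit = list(minPhotons = 100, spatialBinning = 1L),
    thresholds = list(low = 30, high = 40),
    stats = list(aggregate = "median"),
    qpcr = list(ctTable = NULL, correctInputFraction = FALSE),
    dripseq = list(readTable = NULL, genomeLength = 16299,
                   binSize = 20, smoothLength = 45, pseudocount = 0.1)
  )
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

sceneFromConfig <- function(cfg, mixture, seed) {
  sc <- cfg$scene
  sceneSpec(
    imageHeight = sc$imageHeight, imageWidth = sc$imageWidth,
    nChannels = sc$nChannels, timeWindow = sc$timeWindow,
    mitoCount = sc$mitoCount, mitoRadiusRange = as.numeric(sc$mitoRadiusRange),
    backgroundPhotonRate = sc$backgroundPhotonRate,
    mitoPhotonBudget = sc$mitoPhotonBudget,
    po2Mixture = mixture,
    truthK = sc$truthK, truthTauMax = sc$truthTauMax,
    tauFloor = sc$tauFloor, shortLifetime = sc$shortLifetime,
    shortFraction = sc$shortFraction, seed = seed)
}

requireArtifact <- function(state, name, stage) {
  if (is.null(state[[name]]))
    stop("stage '", stage, "' requires missing artifact '", name,
         "'; run its producing stage first", call. = FALSE)
  state[[name]]
}

logStage <- function(level, stage, msg) {
  if (level != "quiet")
    message(sprintf("[flimox] %-10s %s", stage, msg))
}

#' Run the synthetic FLIM oxygen-mapping pipeline
#'
#' Orchestrates simulate -> fit -> calibrate -> po2map -> summarize (plus
#' optional \code{qpcr} and \code{dripsignal} stages) into one reproducible
#' run. Every artifact is written under the output directory; a
#' machine-readable JSON report records the fully resolved configuration,
#' the seed, file digests and the key outputs (calibration K and tau_max,
#' subpopulation fractions, test p-value), which is sufficient to re-execute
#' the run bit-identically.
#'
#' @param config a nested list or path to a YAML file; merged over
#'   [defaultRunConfig()].
#' @param seed optional override of the config seed.
#' @param outDir optional override of the config output directory.
#' @param logLevel \code{"info"} (default) or \code{"quiet"}.
#' @return the run report, invisibly also written to
#'   \code{<outDir>/report.json}.
#' @seealso [runDemo()] for a one-call demonstration run.
#' @export
runPipeline <- function(config = list(), seed = NULL, outDir = NULL,
                        logLevel = "info") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultRunConfig(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outDir)) cfg$outDir <- outDir
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)

  state <- new.env(parent = emptyenv())
  report <- list(
    package = "flimox",
    version = as.character(utils::packageVersion("flimox")),
    seed = cfg$seed,
    parameters = cfg,
    stages = character(0),
    keyOutputs = list(),
    files = list())

  for (stage in cfg$stages) {
    report$stages <- c(report$stages, stage)
    switch(stage,
      simulate = {
        imgDir <- file.path(cfg$outDir, "images")
        dir.create(imgDir, showWarnings = FALSE)
        sims <- list()
        condNames <- names(cfg$conditions)
        for (ci in seq_along(condNames)) {
          cn <- condNames[ci]
          cc <- cfg$conditions[[cn]]
          mixture <- data.frame(weight = as.numeric(cc$weights),
                                mean = as.numeric(cc$means),
                                sd = as.numeric(cc$sds))
          sims[[cn]] <- lapply(seq_len(cc$nImages), function(i) {
            spec <- sceneFromConfig(cfg, mixture,
                                    childSeed(cfg$seed, ci * 1000L + i))
            sim <- generateDecayImage(spec, condition = cn)
            tf <- file.path(imgDir, sprintf("%s_%02d.tiff", cn, i))
            writeTCSPC(sim$image, tf)
            saveRDS(sim$truth, sub("\\.tiff$", "_truth.rds", tf))
            sim
          })
        }
        state$images <- sims
        calSpec <- sceneFromConfig(
          cfg, data.frame(weight = 1, mean = 0, sd = 0),
          childSeed(cfg$seed, 999983L))
        state$calibSeries <- generateCalibrationSeries(
          calSpec, as.numeric(cfg$calibration$levels))
        for (s in state$calibSeries)
          writeTCSPC(s$image, file.path(
            imgDir, sprintf("rotenone_pO2_%g.tiff", s$imposedPO2)))
        logStage(logLevel, stage,
                 sprintf("%d condition images + %d calibration levels",
                         sum(vapply(sims, length, 1L)),
                         length(state$calibSeries)))
      },
      fit = {
        sims <- requireArtifact(state, "images", stage)
        fp <- cfg$fit
        state$fits <- lapply(sims, function(cond) lapply(cond, function(s)
          fitImage(s$image, minPhotons = fp$minPhotons,
                   spatialBinning = fp$spatialBinning)))
        state$calibFits <- lapply(
          requireArtifact(state, "calibSeries", stage),
          function(s) fitImage(s$image, minPhotons = fp$minPhotons,
                               spatialBinning = fp$spatialBinning))
        logStage(logLevel, stage, "per-pixel biexponential fits done")
      },
      calibrate = {
        calFits <- requireArtifact(state, "calibFits", stage)
        series <- requireArtifact(state, "calibSeries", stage)
        pts <- data.frame(
          imposedPO2 = vapply(series, function(s) s$imposedPO2, 1),
          tau = vapply(calFits, function(f)
            mean(f@tauMean[f@mask]), 1),
          nPixels = vapply(calFits, function(f) sum(f@mask), 1))
        state$calibration <- fitCalibration(pts,
                                            tauFloor = cfg$scene$tauFloor)
        report$keyOutputs$K <- state$calibration@K
        report$keyOutputs$tauMax <- state$calibration@tauMax
        logStage(logLevel, stage,
                 sprintf("K = %.3f mmHg, tauMax = %.4f ns",
                         state$calibration@K, state$calibration@tauMax))
      },
      po2map = {
        fits <- requireArtifact(state, "fits", stage)
        calib <- requireArtifact(state, "calibration", stage)
        state$maps <- lapply(fits, function(cond)
          lapply(cond, function(f) po2Map(f, calib)))
        mapDir <- file.path(cfg$outDir, "maps")
        dir.create(mapDir, showWarnings = FALSE)
        for (cn in names(state$maps))
          for (i in seq_along(state$maps[[cn]]))
            renderPseudocolor(state$maps[[cn]][[i]],
                              file.path(mapDir,
                                        sprintf("%s_%02d_po2.png", cn, i)),
                              limits = c(0, 100))
        logStage(logLevel, stage, "oxygen maps rendered")
      },
      summarize = {
        maps <- requireArtifact(state, "maps", stage)
        thr <- cfg$thresholds
        fracs <- lapply(maps, function(cond) vapply(cond, function(m)
          subpopulationFractions(m, thr$low, thr$high)@highOCR, 1))
        medians <- lapply(maps, function(cond) vapply(cond, function(m)
          stats::median(m@po2[m@mask]), 1))
        report$keyOutputs$highOCRFraction <-
          lapply(fracs, function(x) mean(x))
        if (length(medians) >= 2L) {
          mw <- mannWhitney(medians[[1L]], medians[[2L]])
          report$keyOutputs$mannWhitneyP <- mw$p.value
        }
        sumTab <- do.call(rbind, lapply(names(fracs), function(cn)
          data.frame(condition = cn, image = seq_along(fracs[[cn]]),
                     highOCRFraction = fracs[[cn]],
                     medianPO2 = medians[[cn]])))
        utils::write.table(sumTab,
                           file.path(cfg$outDir, "subpopulations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        state$summary <- sumTab
        logStage(logLevel, stage, "subpopulation summary written")
      },
      qpcr = {
        if (is.null(cfg$qpcr$ctTable))
          stop("stage 'qpcr' requires missing artifact 'ctTable' ",
               "(set qpcr$ctTable in the config)", call. = FALSE)
        tab <- readCtTable(cfg$qpcr$ctTable)
        res <- enrichmentTable(tab,
          correctInputFraction = isTRUE(cfg$qpcr$correctInputFraction))
        utils::write.table(res, file.path(cfg$outDir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        state$enrichment <- res
        logStage(logLevel, stage,
                 sprintf("%d enrichment values", nrow(res)))
      },
      dripsignal = {
        if (is.null(cfg$dripseq$readTable))
          stop("stage 'dripsignal' requires missing artifact 'readTable' ",
               "(set dripseq$readTable in the config)", call. = FALSE)
        reads <- readReadTable(cfg$dripseq$readTable)
        sig <- binnedRPKM(reads, cfg$dripseq$genomeLength,
                          cfg$dripseq$binSize)
        sig <- smoothSignal(sig, cfg$dripseq$smoothLength)
        writeBedGraph(sig, file.path(cfg$outDir, "drip_signal.bedgraph"))
        state$dripSignal <- sig
        logStage(logLevel, stage, "binned/smoothed signal written")
      },
      stop("unknown pipeline stage '", stage, "'", call. = FALSE))
  }

  written <- list.files(cfg$outDir, recursive = TRUE, full.names = TRUE)
  written <- setdiff(written, file.path(cfg$outDir, "report.json"))
  digests <- tools::md5sum(written)
  report$files <- as.list(stats::setNames(unname(digests),
                                          basename(names(digests))))
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

#' Compute a DRIP-qPCR enrichment table
#'
#' For every (sample, target) pair in a Ct table, forms the
#' dilution-corrected IP/input ratio and, when an \code{RNaseH-IP} record is
#' present, its RNaseH-normalized value.
#'
#' @param ctTable data.frame in the [readCtTable()] layout.
#' @param correctInputFraction see [dripEnrichment()].
#' @param inputFraction input fraction for the correction (default 0.02).
#' @return data.frame with columns \code{sample}, \code{target},
#'   \code{ipOverInput}, \code{rnasehNormalized}.
#' @export
enrichmentTable <- function(ctTable, correctInputFraction = FALSE,
                            inputFraction = 0.02) {
  keys <- unique(ctTable[, c("sample", "target")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ctTable[ctTable$sample == keys$sample[i] &
                     ctTable$target == keys$target[i], , drop = FALSE]
    pick <- function(role) {
      r <- sub[sub$role == role, , drop = FALSE]
      if (nrow(r) == 0L) NULL
      else ctRecordFromRow(r[1L, , drop = FALSE], inputFraction)
    }
    ip <- pick("IP"); inp <- pick("input"); rh <- pick("RNaseH-IP")
    if (is.null(ip) || is.null(inp)) return(NULL)
    enr <- dripEnrichment(ip, inp, correctInputFraction)
    if (!is.null(rh)) {
      enrRh <- dripEnrichment(rh, inp, correctInputFraction)
      enr <- rnasehNormalize(enr, enrRh)
    }
    data.frame(sample = enr@sample, target = enr@target,
               ipOverInput = enr@ipOverInput,
               rnasehNormalized = enr@rnasehNormalized)
  })
  do.call(rbind, out)
}

#' One-call demonstration run
#'
#' Runs the full synthetic wild-type vs knockout experiment (simulate, fit,
#' calibrate, map, summarize) with the default configuration into
#' \code{outDir}.
#'
#' @param outDir output directory.
#' @param seed integer seed (default 1).
#' @param logLevel \code{"info"} or \code{"quiet"}.
#' @return the run report, invisibly.
#' @export
runDemo <- function(outDir, seed = 1L, logLevel = "info") {
  runPipeline(list(), seed = seed, outDir = outDir, logLevel = logLevel)
}
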