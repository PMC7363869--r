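#' Run the full pipeline
#'
#' Executes the end-to-end workflow under one configuration:
#' simulate (unless an occurrence directory is configured) -> predictor
#' preparation with collinearity screening per tier -> per-species
#' two-tier hierarchical ensembles -> richness stacking and
#' priority-management zoning -> MESS / ignorance uncertainty surfaces
#' -> consolidated report tables. Every stage derives its seed from the
#' master seed via [childSeed()] and logs its parameters, so reruns
#' under an identical configuration reproduce every numeric output.
#' Species that fail their minimum-presence check are skipped and the
#' run continues.
#'
#' @param config a [runConfig()] list.
#' @param outputDir run directory; defaults to `config$outputDir`.
#' @return invisibly, a list with `dir`, `metrics` (consolidated
#'   data.frame), `results` (per-species [SpeciesRunResult-class]),
#'   `zones` ([ZoneMap-class] or `NULL`), `zoneStatistics`,
#'   `variantComparisons`.
#' @export
runPipeline <- function(config = demoRunConfig(),
                        outputDir = config$outputDir) {
  if (is.na(outputDir)) stop("no output directory configured")
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("env", "occurrences", "selection", "species", "zoning",
              "uncertainty", "report"))
    dir.create(file.path(outputDir, d), showWarnings = FALSE)
  logPath <- file.path(outputDir, "log.txt")
  logLines <- character()
  say <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  writeRunConfig(config, file.path(outputDir, "config.yaml"))
  seed <- config$masterSeed
  worldGrid <- asGridSpec(config$worldGrid)
  regionGrid <- asGridSpec(config$regionGrid)
  say("run: master seed %d, world %dx%d, region %dx%d, cell %g deg",
      seed, worldGrid@nRows, worldGrid@nCols, regionGrid@nRows,
      regionGrid@nCols, worldGrid@cellSize)

  ## simulate ----------------------------------------------------------
  env <- config$environment
  worldStack <- generateEnvironment(worldGrid, env$nClimate,
                                    env$nHabitat,
                                    env$autocorrRangeCells,
                                    env$duplicatePairs,
                                    seed = childSeed(seed, "environment"))
  for (nm in layerNames(worldStack))
    writeRaster(worldStack@layers[[nm]],
                file.path(outputDir, "env", paste0(nm, ".grd")))
  say("environment: %d layer(s) [%s]", length(layerNames(worldStack)),
      paste(layerNames(worldStack), collapse = ", "))
  recordsBySpecies <- list()
  truthBySpecies <- list()
  for (sp in config$species) {
    if (!is.na(config$occurrenceDir)) {
      path <- file.path(config$occurrenceDir, paste0(sp$name, ".csv"))
      recs <- if (file.exists(path)) readOccurrences(path)
              else {
                say("occurrences: no file for '%s', species will be skipped",
                    sp$name)
                data.frame(species = character(),
                           decimalLongitude = numeric(),
                           decimalLatitude = numeric(),
                           coordinateUncertaintyInMeters = numeric(),
                           basisOfRecord = character())
              }
    } else {
      spCfg <- speciesConfigFromList(sp, childSeed(seed, "simulate",
                                                   sp$name))
      truth <- trueSuitability(worldStack, spCfg)
      bias <- if (!is.na(spCfg@biasLayerName))
        rasterLayer(worldGrid,
                    stats::plogis(1.5 *
                      worldStack@layers[[spCfg@biasLayerName]]@values),
                    "bias")
      truthBySpecies[[sp$name]] <- truth
      recs <- sampleOccurrences(truth, spCfg,
                                bias = if (!is.na(spCfg@biasLayerName))
                                  bias)
      writeOccurrences(recs, file.path(outputDir, "occurrences",
                                       paste0(sp$name, ".csv")))
    }
    recordsBySpecies[[sp$name]] <- recs
    say("occurrences: %s, %d raw record(s)", sp$name, nrow(recs))
  }

  ## prepare -----------------------------------------------------------
  worldTier <- buildTierStack(worldStack, "global_climatic",
                              config$vifThreshold)
  regionStack <- cropToGrid(worldStack, regionGrid)
  regionTier <- buildTierStack(regionStack, "regional_full",
                               config$vifThreshold)
  writeSelectionReport(worldTier$selection,
                       file.path(outputDir, "selection", "global.csv"))
  writeSelectionReport(regionTier$selection,
                       file.path(outputDir, "selection", "regional.csv"))
  say("predictors: global tier keeps [%s], regional tier keeps [%s]",
      paste(worldTier$selection@retained, collapse = ", "),
      paste(regionTier$selection@retained, collapse = ", "))

  ## per-species hierarchy ---------------------------------------------
  results <- list()
  metrics <- list()
  ledger <- list()
  variantComparisons <- list()
  for (spName in names(recordsBySpecies)) {
    res <- runSpecies(recordsBySpecies[[spName]], worldTier, regionTier,
                      config, masterSeed = seed)
    results[[spName]] <- res
    ledger[[spName]] <- rbind(provenanceLedger(res@occGlobal),
                              provenanceLedger(res@occRegional))
    if (res@skipped) {
      say("species %s: skipped (%s)", spName, res@reason)
      next
    }
    spDir <- file.path(outputDir, "species", spName)
    dir.create(spDir, showWarnings = FALSE)
    writeRaster(res@global@suitability,
                file.path(spDir, "global_suitability.grd"))
    writeRaster(res@global@binary, file.path(spDir, "global_binary.grd"))
    writeRaster(res@regional@suitability,
                file.path(spDir, "regional_suitability.grd"))
    writeRaster(res@regional@binary,
                file.path(spDir, "regional_binary.grd"))
    writeRaster(res@regional@cv, file.path(spDir, "regional_cv.grd"))
    writeRaster(res@projG, file.path(spDir, "projG.grd"))
    m <- speciesRunMetrics(res, config)
    utils::write.csv(m, file.path(spDir, "metrics.csv"),
                     row.names = FALSE)
    metrics[[spName]] <- m
    say("species %s: global TSS %.3f (%d members), regional TSS %.3f (%d members)",
        spName, res@global@tss, res@global@nMembersUsed,
        res@regional@tss, res@regional@nMembersUsed)
    if (isTRUE(config$compareVariants)) {
      cmp <- compareVariants(recordsBySpecies[[spName]], worldTier,
                             regionTier, config)
      variantComparisons[[spName]] <- cmp
      say("species %s: variant Bhattacharyya distance %s", spName,
          cmp$formatted)
    }
  }
  utils::write.csv(do.call(rbind, ledger),
                   file.path(outputDir, "occurrences", "ledger.csv"),
                   row.names = FALSE)
  ran <- Filter(function(r) !r@skipped, results)

  ## zoning + uncertainty ----------------------------------------------
  zones <- NULL
  zoneStats <- NULL
  if (length(ran)) {
    regionalBinaries <- lapply(ran, function(r) r@regional@binary)
    globalBinaries <- lapply(ran, function(r)
      projectLayer(r@global@binary, regionGrid))
    cvLayers <- lapply(ran, function(r) r@regional@cv)
    richR <- stackRichness(regionalBinaries, "richness_regional")
    richG <- stackRichness(globalBinaries, "richness_global")
    meanCv <- meanCvMap(cvLayers)
    rt <- if (is.na(config$richnessThreshold)) NULL
          else config$richnessThreshold
    zones <- classifyZones(meanCv, richR, richG,
                           cvThreshold = config$cvThreshold,
                           richnessThreshold = rt,
                           nSpecies = length(ran))
    messLayers <- lapply(ran, function(r) {
      refCells <- presenceCells(r@occRegional)
      ref <- stackValues(regionTier$stack)[refCells, , drop = FALSE]
      messLayer(ref, regionTier$stack)
    })
    messProp <- messProportion(messLayers)
    cleanedAll <- do.call(rbind, lapply(recordsBySpecies, function(r)
      cleanCoordinates(filterRecords(r, "certain_plus_NA",
                                     config$maxUncertaintyM),
                       exclusionPointsFrame(config$exclusionPoints))))
    ign <- ignoranceMap(cleanedAll, regionGrid,
                        config$ignoranceHalfSaturation)
    zoneStats <- zoneStatistics(zones, list(mess = messProp,
                                            ignorance = ignoranceLayer(ign, rescaled = TRUE),
                                            cv = meanCv))
    writeRaster(richR, file.path(outputDir, "zoning",
                                 "richness_regional.grd"))
    writeRaster(richG, file.path(outputDir, "zoning",
                                 "richness_global.grd"))
    writeRaster(meanCv, file.path(outputDir, "zoning", "mean_cv.grd"))
    writeRaster(zoneLayer(zones), file.path(outputDir, "zoning",
                                            "zones.grd"))
    utils::write.csv(zoneLegend(),
                     file.path(outputDir, "zoning", "zone_legend.csv"),
                     row.names = FALSE)
    utils::write.csv(zoneStats,
                     file.path(outputDir, "zoning",
                               "zone_statistics.csv"), row.names = FALSE)
    writeRaster(messProp, file.path(outputDir, "uncertainty",
                                    "mess_proportion.grd"))
    writeRaster(ignoranceLayer(ign), file.path(outputDir, "uncertainty",
                                               "ignorance.grd"))
    writeRaster(ignoranceLayer(ign, rescaled = TRUE),
                file.path(outputDir, "uncertainty",
                          "ignorance_rescaled.grd"))
    say("zoning: %d species stacked, thresholds CV > %g, richness > %g",
        length(ran), zones@cvThreshold, zones@richnessThreshold)
  } else {
    say("zoning: skipped, no species completed")
  }
  if (length(variantComparisons)) {
    cmpTable <- data.frame(
      species = names(variantComparisons),
      bhattacharyya = vapply(variantComparisons,
                             function(x) x$bhattacharyya, numeric(1)),
      stringsAsFactors = FALSE)
    utils::write.csv(cmpTable,
                     file.path(outputDir, "report",
                               "variant_distances.csv"),
                     row.names = FALSE)
  }
  writeLines(logLines, logPath)
  report <- buildReport(outputDir)
  invisible(list(dir = outputDir,
                 metrics = if (length(metrics)) do.call(rbind, metrics)
                           else data.frame(),
                 results = results, zones = zones,
                 zoneStatistics = zoneStats,
                 variantComparisons = variantComparisons,
                 report = report))
}

#' Assemble the consolidated report tables of a completed run
#'
#' Reads the per-species metrics and zoning statistics from a run
#' directory and writes the consolidated CSVs: the regional metrics
#' table (columns `n`, `TSS`, `Sensitivity`, `Specificity`,
#' `Cut-off binary`, `Mean CV`, `Range filling`, sensitivity and
#' specificity on the percent scale), the global metrics table (same
#' minus range filling), the per-zone uncertainty statistics
#' (mean/min/max of MESS proportion, ignorance and CV per zone) and the
#' zone area fractions.
#'
#' @param runDir a directory produced by [runPipeline()].
#' @return invisibly, a list of the four data.frames.
#' @export
buildReport <- function(runDir) {
  spDir <- file.path(runDir, "species")
  if (!dir.exists(spDir))
    stop("incomplete run: missing stage directory 'species'")
  files <- list.files(spDir, pattern = "^metrics\\.csv$",
                      recursive = TRUE, full.names = TRUE)
  metrics <- if (length(files))
    do.call(rbind, lapply(files, utils::read.csv,
                          stringsAsFactors = FALSE))
  else data.frame()
  fmtTier <- function(m, withRange) {
    out <- data.frame(Species = m$species, n = m$n, TSS = round(m$tss, 2),
                      Sensitivity = round(100 * m$sensitivity, 2),
                      Specificity = round(100 * m$specificity, 2),
                      check.names = FALSE, stringsAsFactors = FALSE)
    out[["Cut-off binary"]] <- round(m$cutoff, 2)
    out[["Mean CV"]] <- round(m$meanCv, 2)
    if (withRange) out[["Range filling"]] <- round(m$rangeFilling, 2)
    out
  }
  regional <- fmtTier(metrics[metrics$tier == "regional_full", ,
                              drop = FALSE], TRUE)
  global <- fmtTier(metrics[metrics$tier == "global_climatic", ,
                            drop = FALSE], FALSE)
  zonesPath <- file.path(runDir, "zoning", "zone_statistics.csv")
  zoneStats <- if (file.exists(zonesPath))
    utils::read.csv(zonesPath, stringsAsFactors = FALSE,
                    check.names = FALSE)
  else data.frame()
  zoneFractions <- if (nrow(zoneStats))
    zoneStats[, c("zone", "label", "nCells", "fraction")]
  else data.frame()
  repDir <- file.path(runDir, "report")
  dir.create(repDir, showWarnings = FALSE)
  utils::write.csv(regional, file.path(repDir, "regional_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(global, file.path(repDir, "global_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(zoneStats, file.path(repDir, "zone_statistics.csv"),
                   row.names = FALSE)
  utils::write.csv(zoneFractions, file.path(repDir,
                                            "zone_fractions.csv"),
                   row.names = FALSE)
  invisible(list(regional = regional, global = global,
                 zoneStatistics = zoneStats,
                 zoneFractions = zoneFractions))
}
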