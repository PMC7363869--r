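#' Pipeline run configuration
#'
#' Collects every parameter of an end-to-end run: the two lattices, the
#' synthetic-environment and virtual-species scenario, per-tier dataset
#' variants and ensemble settings, the cleaning / collinearity /
#' zoning thresholds, and the master seed from which every stage's seed
#' derives via [childSeed()]. The structure round-trips losslessly
#' through [writeRunConfig()] / [readRunConfig()].
#'
#' @param worldGrid,regionGrid lists with `minLon`, `minLat`,
#'   `cellSize`, `nRows`, `nCols`; the region must be an aligned
#'   sub-extent of the world.
#' @param environment list with `nClimate`, `nHabitat`,
#'   `autocorrRangeCells`, `duplicatePairs` for [generateEnvironment()].
#' @param species list of per-species scenario lists: `name`, `family`,
#'   `linear` (named list of linear coefficients), `quadratic`,
#'   `prevalenceTarget`, `nRecords`, `biasLayerName`,
#'   `pMissingUncertainty`, `uncertaintyLogMean`, `uncertaintyLogSd`,
#'   `pErrorRecords`.
#' @param occurrenceDir optional directory of per-species occurrence
#'   CSVs (named `<species>.csv`); when set, simulation is skipped.
#' @param globalVariant,regionalVariant dataset variant per tier.
#' @param maxUncertaintyM coordinate-precision threshold (metres,
#'   inclusive).
#' @param vifThreshold collinearity-removal threshold.
#' @param minPresences minimum presence cells to model a species.
#' @param exclusionPoints list of lists with `lon`, `lat`, `radiusM`.
#' @param globalEnsemble,regionalEnsemble [ensembleConfig()] lists;
#'   the classical study sizes are 20,000 and 5,000 pseudo-absences.
#' @param cvThreshold,richnessThreshold zoning thresholds ("high" is
#'   strictly greater); `richnessThreshold = NA` means the central
#'   value `floor(nSpecies / 2)`.
#' @param ignoranceHalfSaturation record count at which the ignorance
#'   index is 0.5.
#' @param compareVariants also run the dataset-variant sensitivity
#'   comparison for each species (doubles the fitting work).
#' @param masterSeed integer.
#' @param outputDir run directory created by [runPipeline()].
#' @return a list of class `runConfig`.
#' @export
runConfig <- function(worldGrid = list(minLon = -2, minLat = -2,
                                       cellSize = 0.25, nRows = 48,
                                       nCols = 48),
                      regionGrid = list(minLon = 0, minLat = 0,
                                        cellSize = 0.25, nRows = 40,
                                        nCols = 40),
                      environment = list(nClimate = 3L, nHabitat = 2L,
                                         autocorrRangeCells = 4,
                                         duplicatePairs = 1L),
                      species = list(),
                      occurrenceDir = NA_character_,
                      globalVariant = "certain_plus_NA",
                      regionalVariant = "certain",
                      maxUncertaintyM = 15000,
                      vifThreshold = 4,
                      minPresences = 30L,
                      exclusionPoints = list(),
                      globalEnsemble = ensembleConfig(nPseudoAbsences = 20000L),
                      regionalEnsemble = ensembleConfig(nPseudoAbsences = 5000L),
                      cvThreshold = 0.5,
                      richnessThreshold = NA_real_,
                      ignoranceHalfSaturation = 1,
                      compareVariants = FALSE,
                      masterSeed = 1L,
                      outputDir = NA_character_) {
  stopifnot(maxUncertaintyM > 0, vifThreshold > 1, minPresences >= 1,
            cvThreshold >= 0, cvThreshold <= 1,
            ignoranceHalfSaturation > 0)
  if (!globalVariant %in% c("certain", "certain_plus_NA") ||
      !regionalVariant %in% c("certain", "certain_plus_NA"))
    stop("variants must be 'certain' or 'certain_plus_NA'")
  structure(list(worldGrid = worldGrid, regionGrid = regionGrid,
                 environment = environment, species = species,
                 occurrenceDir = occurrenceDir,
                 globalVariant = globalVariant,
                 regionalVariant = regionalVariant,
                 maxUncertaintyM = maxUncertaintyM,
                 vifThreshold = vifThreshold,
                 minPresences = as.integer(minPresences),
                 exclusionPoints = exclusionPoints,
                 globalEnsemble = globalEnsemble,
                 regionalEnsemble = regionalEnsemble,
                 cvThreshold = cvThreshold,
                 richnessThreshold = richnessThreshold,
                 ignoranceHalfSaturation = ignoranceHalfSaturation,
                 compareVariants = compareVariants,
                 masterSeed = as.integer(masterSeed),
                 outputDir = outputDir),
            class = "runConfig")
}

#' @describeIn runConfig materialize a grid list into a
#'   [GridSpec-class].
#' @param x a grid list (`minLon`, `minLat`, `cellSize`, `nRows`,
#'   `nCols`).
#' @export
asGridSpec <- function(x) {
  gridSpec(x$minLon, x$minLat, x$cellSize, x$nRows, x$nCols)
}

exclusionPointsFrame <- function(x) {
  if (is.null(x) || !length(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, as.data.frame))
}

speciesConfigFromList <- function(sp, seed) {
  virtualSpeciesConfig(
    speciesName = sp$name,
    family = if (is.null(sp$family)) "Synthetica" else sp$family,
    linearCoefficients = unlist(sp$linear),
    quadraticCoefficients = if (is.null(sp$quadratic)) numeric()
                            else unlist(sp$quadratic),
    prevalenceTarget = if (is.null(sp$prevalenceTarget)) NA_real_
                       else sp$prevalenceTarget,
    nRecords = if (is.null(sp$nRecords)) 500L else sp$nRecords,
    biasLayerName = if (is.null(sp$biasLayerName)) NA_character_
                    else sp$biasLayerName,
    pMissingUncertainty = if (is.null(sp$pMissingUncertainty)) 0.3
                          else sp$pMissingUncertainty,
    uncertaintyLogMean = if (is.null(sp$uncertaintyLogMean)) log(5000)
                         else sp$uncertaintyLogMean,
    uncertaintyLogSd = if (is.null(sp$uncertaintyLogSd)) 1
                       else sp$uncertaintyLogSd,
    pErrorRecords = if (is.null(sp$pErrorRecords)) 0.05
                    else sp$pErrorRecords,
    seed = seed)
}

#' Read and write run configurations
#'
#' YAML serialization of a [runConfig()]; reading re-validates and
#' restores the configuration losslessly.
#'
#' @param config a [runConfig()] list.
#' @param path YAML file path.
#' @return `readRunConfig` returns the [runConfig()];
#'   `writeRunConfig` returns `path` invisibly.
#' @export
writeRunConfig <- function(config, path) {
  plain <- unclass(config)
  plain$globalEnsemble <- unclass(plain$globalEnsemble)
  plain$regionalEnsemble <- unclass(plain$regionalEnsemble)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$globalEnsemble <- do.call(ensembleConfig, x$globalEnsemble)
  x$regionalEnsemble <- do.call(ensembleConfig, x$regionalEnsemble)
  do.call(runConfig, x)
}

#' Desk-scale demonstration configuration
#'
#' Two virtual species on a 48 x 48 world with a 40 x 40 region: one
#' driven by climate alone, one additionally constrained by a habitat
#' layer (so the regional model has information the global one lacks).
#' One planted near-duplicate climate layer exercises the collinearity
#' screen, sampling is biased by a habitat surface, and the occurrence
#' tables carry missing uncertainties and injected coordinate errors.
#' Ensemble sizes are scaled to run in about a minute.
#'
#' @param masterSeed integer.
#' @param outputDir run directory (default: fresh temporary directory).
#' @return a [runConfig()] list.
#' @export
demoRunConfig <- function(masterSeed = 1L,
                          outputDir = file.path(tempdir(),
                                                paste0("hierSDM-demo-",
                                                       masterSeed))) {
  demoEnsemble <- function(nPa)
    ensembleConfig(nPseudoAbsences = nPa, nPaSets = 2L, nCvRuns = 2L,
                   gbmTrees = 150L, gbmShrinkage = 0.1)
  runConfig(
    species = list(
      list(name = "virtualis_clima", family = "Virtualidae",
           linear = list(climate1 = 2, climate2 = -2, climate3 = 2),
           prevalenceTarget = 0.12, nRecords = 600L,
           biasLayerName = "habitat2"),
      list(name = "virtualis_silva", family = "Virtualidae",
           linear = list(climate1 = 2, climate2 = -2, habitat1 = 2,
                         habitat2 = -2),
           prevalenceTarget = 0.12, nRecords = 600L,
           biasLayerName = "habitat2")),
    globalEnsemble = demoEnsemble(600L),
    regionalEnsemble = demoEnsemble(400L),
    masterSeed = masterSeed, outputDir = outputDir)
}
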