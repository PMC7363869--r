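# Shared fixtures and study scenarios, all generated in code.

quickEnsemble <- function(algorithms = c("glm_logistic", "fda"),
                          nPseudoAbsences = 150L, nPaSets = 1L,
                          nCvRuns = 2L) {
  ensembleConfig(algorithms = algorithms,
                 nPseudoAbsences = nPseudoAbsences, nPaSets = nPaSets,
                 nCvRuns = nCvRuns, gbmTrees = 60L, gbmShrinkage = 0.1)
}

# hand-built record table; every argument recycles
makeRecords <- function(lon, lat, unc = 100,
                        basis = "human_observation", species = "sp",
                        family = "Fam") {
  n <- max(length(lon), length(lat))
  data.frame(species = rep_len(species, n),
             decimalLongitude = rep_len(lon, n),
             decimalLatitude = rep_len(lat, n),
             coordinateUncertaintyInMeters = rep_len(unc, n),
             basisOfRecord = rep_len(basis, n),
             family = rep_len(family, n),
             stringsAsFactors = FALSE)
}

# Parameter-recovery study: a climatically restricted virtual species
# with a steep four-gradient envelope (|beta| = 2 on each climate
# layer, prevalence 0.10) on a 40 x 40 grid, 500 clean presence
# records, 2 x 1,000 pseudo-absence cells.
recoveryScenario <- function(seed) {
  g <- gridSpec(0, 0, 0.25, 40, 40)
  st <- generateEnvironment(g, nClimate = 4, nHabitat = 2,
                            autocorrRangeCells = 4, duplicatePairs = 0,
                            seed = childSeed(seed, "env"))
  cfg <- virtualSpeciesConfig(
    "recovery_vsp",
    linearCoefficients = c(climate1 = 2, climate2 = -2, climate3 = 2,
                           climate4 = -2),
    prevalenceTarget = 0.10, nRecords = 500L, pErrorRecords = 0,
    pMissingUncertainty = 0, seed = seed)
  truth <- trueSuitability(st, cfg)
  records <- sampleOccurrences(truth, cfg)
  list(grid = g, stack = st, truth = truth, records = records,
       ensemble = ensembleConfig(nPseudoAbsences = 1000L, nPaSets = 2L,
                                 nCvRuns = 2L, gbmTrees = 150L,
                                 gbmShrinkage = 0.1))
}

# Two-tier study with introduced-range geometry: a wide world whose
# first climate layer carries a longitudinal trend, the region at the
# climatically favorable end, and a species additionally constrained
# by two habitat layers the global tier never sees.
hierarchyScenario <- function(seed) {
  wg <- gridSpec(-14, -2, 0.25, 48, 96)
  rg <- gridSpec(0, 0, 0.25, 40, 40)
  st <- generateEnvironment(wg, nClimate = 3, nHabitat = 2,
                            autocorrRangeCells = 4, duplicatePairs = 0,
                            seed = childSeed(seed, "env"))
  lon <- cellCenter(wg, seq_len(nCells(wg)))$lon
  trend <- (lon - mean(lon)) / stats::sd(lon)
  v <- layerValues(st@layers[["climate1"]]) + 1.5 * trend
  st@layers[["climate1"]] <- rasterLayer(wg, (v - mean(v)) / stats::sd(v),
                                         "climate1")
  cfg <- virtualSpeciesConfig(
    "hierarchy_vsp",
    linearCoefficients = c(climate1 = 2, climate2 = -2, habitat1 = 2,
                           habitat2 = -2),
    prevalenceTarget = 0.10, nRecords = 800L, pErrorRecords = 0.05,
    pMissingUncertainty = 0.3, seed = seed)
  truth <- trueSuitability(st, cfg)
  records <- sampleOccurrences(truth, cfg)
  mkEns <- function(nPa) ensembleConfig(nPseudoAbsences = nPa,
                                        nPaSets = 3L, nCvRuns = 2L,
                                        gbmTrees = 150L,
                                        gbmShrinkage = 0.1)
  config <- runConfig(globalEnsemble = mkEns(1000L),
                      regionalEnsemble = mkEns(600L), masterSeed = seed)
  list(worldGrid = wg, regionGrid = rg, stack = st, truth = truth,
       records = records, config = config)
}
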