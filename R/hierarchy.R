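#' Run the two-tier hierarchical procedure for one species
#'
#' Implements the per-species feed-forward workflow: (1) filter / clean
#' / thin the records against the world grid under the global dataset
#' variant (default `certain_plus_NA`, maximizing the sampled climatic
#' niche) and against the region grid under the regional variant
#' (default `certain`, prioritizing precision); (2) fit the global
#' climate-only ensemble; (3) project its committee suitability onto
#' the region lattice; (4) weight the regional pseudo-absences by that
#' projection through the inverse-logistic weight; (5) fit the regional
#' full-predictor ensemble. The regional model only ever consumes cells
#' of the region grid.
#'
#' @param records raw occurrence data.frame for one species.
#' @param worldTier,regionTier tier lists from [buildTierStack()]
#'   (elements `stack`, `selection`) for the global and regional
#'   extents.
#' @param config a [runConfig()] list.
#' @param masterSeed integer; overrides `config$masterSeed` when given.
#' @return a [SpeciesRunResult-class]; when the species has fewer
#'   presence cells than `config$minPresences` the result has
#'   `skipped = TRUE` and a reason, and no model slots.
#' @export
runSpecies <- function(records, worldTier, regionTier, config = runConfig(),
                       masterSeed = NULL) {
  seed <- as.integer(if (is.null(masterSeed)) config$masterSeed
                     else masterSeed)
  species <- if (nrow(records)) records$species[1] else "unknown"
  worldStack <- worldTier$stack
  regionStack <- regionTier$stack
  excl <- exclusionPointsFrame(config$exclusionPoints)
  occG <- prepareOccurrences(records, worldStack@grid,
                             config$globalVariant,
                             config$maxUncertaintyM, excl)
  occR <- prepareOccurrences(records, regionStack@grid,
                             config$regionalVariant,
                             config$maxUncertaintyM, excl)
  skip <- function(reason) {
    message("skipping species '", species, "': ", reason)
    new("SpeciesRunResult", species = species, skipped = TRUE,
        reason = reason, global = NULL, regional = NULL, projG = NULL,
        occGlobal = occG, occRegional = occR, seed = seed)
  }
  if (length(presenceCells(occG)) < config$minPresences)
    return(skip(sprintf("only %d global presence cells (minimum %d)",
                        length(presenceCells(occG)), config$minPresences)))
  if (length(presenceCells(occR)) < config$minPresences)
    return(skip(sprintf("only %d regional presence cells (minimum %d)",
                        length(presenceCells(occR)), config$minPresences)))
  global <- fitEnsemble(presenceCells(occG), worldStack,
                        config$globalEnsemble,
                        seed = childSeed(seed, species, "global"),
                        tier = "global_climatic")
  projG <- projectLayer(global@suitability, regionStack@grid)
  regional <- fitEnsemble(presenceCells(occR), regionStack,
                          config$regionalEnsemble,
                          seed = childSeed(seed, species, "regional"),
                          projG = projG, tier = "regional_full")
  new("SpeciesRunResult", species = species, skipped = FALSE,
      reason = "", global = global, regional = regional, projG = projG,
      occGlobal = occG, occRegional = occR, seed = seed)
}

setMethod("show", "SpeciesRunResult", function(object) {
  if (object@skipped) {
    cat(sprintf("SpeciesRunResult '%s': skipped (%s)\n", object@species,
                object@reason))
  } else {
    cat(sprintf("SpeciesRunResult '%s' (seed %d)\n  global:   TSS %.3f\n  regional: TSS %.3f\n",
                object@species, object@seed, object@global@tss,
                object@regional@tss))
  }
})

#' Metrics of a species run as a data.frame
#' @param result a [SpeciesRunResult-class].
#' @param config the [runConfig()] the run used (for variant labels).
#' @return a data.frame with one row per tier (empty when skipped).
#' @export
speciesRunMetrics <- function(result, config = runConfig()) {
  if (result@skipped) return(data.frame())
  rbind(
    ensembleMetrics(result@global, n = length(presenceCells(result@occGlobal)),
                    species = result@species,
                    variant = config$globalVariant),
    ensembleMetrics(result@regional,
                    n = length(presenceCells(result@occRegional)),
                    species = result@species,
                    variant = config$regionalVariant))
}

#' Compare dataset-variant choices for one species
#'
#' Re-runs the full two-tier procedure under two dataset-variant
#' policies with the same master seed, reports the metrics side by
#' side, and measures the divergence of the continuous regional
#' suitability maps with the Bhattacharyya distance. With identical
#' effective inputs (e.g. no records of unknown uncertainty) the two
#' runs coincide and the distance is 0.
#'
#' @param records raw occurrence data.frame for one species.
#' @param worldTier,regionTier tier lists from [buildTierStack()].
#' @param config a [runConfig()] list.
#' @param variantA,variantB lists with elements `global` and `regional`
#'   naming the dataset variant per tier.
#' @return a list with `metrics` (data.frame, one row per variant and
#'   tier), `bhattacharyya` (numeric) and `formatted` (the distance
#'   printed to 4 decimals).
#' @export
compareVariants <- function(records, worldTier, regionTier,
                            config = runConfig(),
                            variantA = list(global = "certain_plus_NA",
                                            regional = "certain"),
                            variantB = list(global = "certain",
                                            regional = "certain")) {
  runWith <- function(v, label) {
    cfg <- config
    cfg$globalVariant <- v$global
    cfg$regionalVariant <- v$regional
    res <- runSpecies(records, worldTier, regionTier, cfg)
    if (res@skipped)
      stop("variant comparison impossible: run ", label, " skipped (",
           res@reason, ")")
    m <- speciesRunMetrics(res, cfg)
    m$variantPolicy <- label
    list(result = res, metrics = m)
  }
  a <- runWith(variantA, "A")
  b <- runWith(variantB, "B")
  d <- bhattacharyyaDistance(a$result@regional@suitability,
                             b$result@regional@suitability)
  list(metrics = rbind(a$metrics, b$metrics), bhattacharyya = d,
       formatted = sprintf("%.4f", d))
}
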