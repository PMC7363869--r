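#' @import methods
NULL

#' Regular geographic lattice
#'
#' A `GridSpec` describes a regular longitude/latitude lattice. Cell
#' `(r, c)` (both 1-based, row 1 at `minLat`, i.e. the southern edge)
#' covers the half-open box
#' `[minLon + (c-1) s, minLon + c s) x [minLat + (r-1) s, minLat + r s)`
#' with `s = cellSize`, so every in-extent point belongs to exactly one
#' cell. Cells are addressed by a 1-based linear index running west to
#' east, then south to north.
#'
#' @slot minLon,minLat numeric, coordinates of the south-west corner
#'   (degrees).
#' @slot cellSize numeric, cell edge in degrees (default 0.25, roughly a
#'   30 km cell at mid latitudes).
#' @slot nRows,nCols integer, lattice dimensions.
#' @slot crs character, geographic CRS identifier (informational).
#' @exportClass GridSpec
setClass("GridSpec",
  representation(minLon = "numeric", minLat = "numeric",
                 cellSize = "numeric", nRows = "integer",
                 nCols = "integer", crs = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "nRows and nCols must be >= 1")
    if (!is.finite(object@minLon) || !is.finite(object@minLat))
      msg <- c(msg, "grid origin must be finite")
    if (length(msg)) msg else TRUE
  })

#' Gridded layer of real values
#'
#' A single named layer on a [GridSpec-class]. Nodata cells are stored
#' as `NA`; the nodata mask is therefore `is.na(layerValues(x))`.
#'
#' @slot grid a [GridSpec-class].
#' @slot name character, layer name.
#' @slot values numeric vector of length `nRows * nCols` in linear cell
#'   order (west to east, south to north); `NA` marks nodata.
#' @exportClass RasterLayer
setClass("RasterLayer",
  representation(grid = "GridSpec", name = "character",
                 values = "numeric"),
  validity = function(object) {
    n <- object@grid@nRows * object@grid@nCols
    if (length(object@values) != n)
      return(sprintf("values has length %d, grid has %d cells",
                     length(object@values), n))
    if (length(object@name) != 1) return("name must be a single string")
    TRUE
  })

#' Ordered collection of layers on one grid
#'
#' @slot grid the shared [GridSpec-class].
#' @slot layers named list of [RasterLayer-class]; names unique, each
#'   layer on the shared grid.
#' @exportClass RasterStack
setClass("RasterStack",
  representation(grid = "GridSpec", layers = "list"),
  validity = function(object) {
    nm <- names(object@layers)
    if (length(object@layers) && (is.null(nm) || anyDuplicated(nm)))
      return("layers must be uniquely named")
    for (ly in object@layers) {
      if (!is(ly, "RasterLayer")) return("layers must be RasterLayer objects")
      if (!identical(ly@grid, object@grid))
        return("all layers must share the stack grid")
    }
    TRUE
  })

#' Virtual species definition
#'
#' Ground-truth suitability is `plogis(intercept + sum(beta * x) +
#' sum(gamma * x^2))` over named predictor layers. The sampling fields
#' control how presence-only records are drawn from that surface:
#' log-normal coordinate uncertainty (metres), a fraction of records
#' with the uncertainty field missing, and a fraction corrupted into one
#' of the three cleanable coordinate-error classes.
#'
#' @slot speciesName,family character.
#' @slot linearCoefficients named numeric, per-predictor linear terms.
#' @slot quadraticCoefficients named numeric (possibly empty).
#' @slot intercept numeric.
#' @slot prevalenceTarget numeric in (0,1) or `NA`; when set the
#'   intercept is re-solved so mean suitability matches it within 0.005.
#' @slot nRecords integer, records to draw.
#' @slot biasLayerName character or `NA`, sampling-bias layer.
#' @slot pMissingUncertainty,pErrorRecords numeric fractions in [0,1].
#' @slot uncertaintyLogMean,uncertaintyLogSd numeric, log-normal
#'   parameters of the coordinate uncertainty in metres.
#' @slot seed integer.
#' @exportClass VirtualSpeciesConfig
setClass("VirtualSpeciesConfig",
  representation(speciesName = "character", family = "character",
                 linearCoefficients = "numeric",
                 quadraticCoefficients = "numeric",
                 intercept = "numeric", prevalenceTarget = "numeric",
                 nRecords = "integer", biasLayerName = "character",
                 pMissingUncertainty = "numeric",
                 uncertaintyLogMean = "numeric",
                 uncertaintyLogSd = "numeric",
                 pErrorRecords = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    frac <- c(pMissingUncertainty = object@pMissingUncertainty,
              pErrorRecords = object@pErrorRecords)
    bad <- frac < 0 | frac > 1
    if (any(bad))
      msg <- c(msg, paste(names(frac)[bad], "must lie in [0, 1]"))
    if (object@nRecords < 1L) msg <- c(msg, "nRecords must be >= 1")
    if (all(c(object@linearCoefficients,
              object@quadraticCoefficients) == 0))
      msg <- c(msg, "at least one coefficient must be nonzero")
    if (length(msg)) msg else TRUE
  })

#' Cleaned per-species presence set
#'
#' Presence cells on a grid after the filter / clean / thin pipeline,
#' with a provenance ledger of record counts at each stage.
#'
#' @slot species character.
#' @slot variant `"certain"` (coordinate uncertainty known and within
#'   the threshold) or `"certain_plus_NA"` (unknown uncertainty also
#'   kept).
#' @slot grid the [GridSpec-class] used for thinning.
#' @slot presenceCells sorted integer cell indices.
#' @slot nRaw,nAfterFilters,nAfterCleaning,nOutside integer counts.
#' @exportClass SpeciesOccurrenceSet
setClass("SpeciesOccurrenceSet",
  representation(species = "character", variant = "character",
                 grid = "GridSpec", presenceCells = "integer",
                 nRaw = "integer", nAfterFilters = "integer",
                 nAfterCleaning = "integer", nOutside = "integer"),
  validity = function(object) {
    if (!object@variant %in% c("certain", "certain_plus_NA"))
      return("variant must be 'certain' or 'certain_plus_NA'")
    n <- c(object@nRaw, object@nAfterFilters, object@nAfterCleaning,
           length(object@presenceCells))
    if (any(diff(n) > 0))
      return("counts must satisfy nRaw >= nAfterFilters >= nAfterCleaning >= nPresenceCells")
    if (is.unsorted(object@presenceCells, strictly = TRUE) &&
        length(object@presenceCells) > 1)
      return("presenceCells must be sorted and unique")
    TRUE
  })

#' Stepwise VIF predictor selection
#'
#' @slot tier character, `"global_climatic"`, `"regional_full"` or
#'   `"unspecified"`.
#' @slot retained character, names kept (original order).
#' @slot dropped data.frame with columns `name` and `vif` (VIF at the
#'   iteration the variable was removed).
#' @slot threshold numeric, removal threshold (default 4).
#' @exportClass PredictorSelection
setClass("PredictorSelection",
  representation(tier = "character", retained = "character",
                 dropped = "data.frame", threshold = "numeric"),
  validity = function(object) {
    if (length(intersect(object@retained, object@dropped$name)))
      return("retained and dropped sets must be disjoint")
    TRUE
  })

#' Pseudo-absence sample with reliability weights
#'
#' @slot id integer, set identifier (1..nPaSets).
#' @slot cells integer cell indices (no presence cells).
#' @slot weights numeric in [0, 1], one per cell; 1 until re-weighted by
#'   a global projection.
#' @exportClass PseudoAbsenceSet
setClass("PseudoAbsenceSet",
  representation(id = "integer", cells = "integer", weights = "numeric"),
  validity = function(object) {
    if (length(object@cells) != length(object@weights))
      return("weights and cells must have equal length")
    if (any(object@weights < 0 | object@weights > 1))
      return("weights must lie in [0, 1]")
    TRUE
  })

#' One fitted ensemble member
#'
#' @slot algorithm character, one of `glm_logistic`, `gam_spline`,
#'   `fda`, `gbm`, `maxent_like`.
#' @slot paSetId,cvRunId integer provenance.
#' @slot fit list, the fitted learner handle plus its input scaling.
#' @slot evalSensitivity,evalSpecificity,evalTss numeric, held-out
#'   metrics at `memberCutoff`.
#' @slot memberCutoff numeric in [0, 1], the TSS-maximizing cutoff on
#'   the evaluation split.
#' @exportClass FittedMember
setClass("FittedMember",
  representation(algorithm = "character", paSetId = "integer",
                 cvRunId = "integer", fit = "list",
                 evalSensitivity = "numeric", evalSpecificity = "numeric",
                 evalTss = "numeric", memberCutoff = "numeric"),
  validity = function(object) {
    if (abs(object@evalTss -
            (object@evalSensitivity + object@evalSpecificity - 1)) > 1e-8)
      return("evalTss must equal evalSensitivity + evalSpecificity - 1")
    TRUE
  })

#' Committee-average ensemble prediction
#'
#' @slot tier character label.
#' @slot suitability [RasterLayer-class], committee average in [0, 1].
#' @slot cv [RasterLayer-class], coefficient of variation of member
#'   binaries, standardized to [0, 1] by the map maximum.
#' @slot binary [RasterLayer-class] in \{0, 1\}: `suitability >= cutoff`.
#' @slot cutoff,tss,sensitivity,specificity numeric, ensemble metrics at
#'   the TSS-maximizing cutoff.
#' @slot meanCv numeric, mean of `cv` over valid cells.
#' @slot rangeFilling numeric, fraction of predicted-presence cells that
#'   hold observed presences (`NA` when no cell is predicted present).
#' @slot nMembersUsed integer.
#' @slot memberTable data.frame, per-member provenance and metrics.
#' @exportClass EnsemblePrediction
setClass("EnsemblePrediction",
  representation(tier = "character", suitability = "RasterLayer",
                 cv = "RasterLayer", binary = "RasterLayer",
                 cutoff = "numeric", tss = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 meanCv = "numeric", rangeFilling = "numeric",
                 nMembersUsed = "integer", memberTable = "data.frame"),
  validity = function(object) {
    s <- object@suitability@values
    b <- object@binary@values
    ok <- !is.na(s) & !is.na(b)
    if (any(b[ok] != as.numeric(s[ok] >= object@cutoff)))
      return("binary must equal suitability >= cutoff")
    TRUE
  })

#' Result of one species' two-tier run
#'
#' @slot species character.
#' @slot skipped logical; when `TRUE` only `reason` is meaningful.
#' @slot reason character.
#' @slot global,regional [EnsemblePrediction-class] (or `NULL` when
#'   skipped).
#' @slot projG [RasterLayer-class], global committee suitability
#'   projected onto the region grid (the Weight() input).
#' @slot occGlobal,occRegional [SpeciesOccurrenceSet-class].
#' @slot seed integer master seed of the run.
#' @exportClass SpeciesRunResult
setClass("SpeciesRunResult",
  representation(species = "character", skipped = "logical",
                 reason = "character", global = "ANY", regional = "ANY",
                 projG = "ANY", occGlobal = "ANY", occRegional = "ANY",
                 seed = "integer"))

#' Priority-management zone map
#'
#' Integer zone codes 1..6 correspond to zones A..F:
#' A coldspot, B hotspot, C uncertain coldspot, D uncertain climatic
#' hotspot, E uncertain environmental hotspot, F uncertain hotspot.
#' `NA` marks masked cells.
#'
#' @slot grid a [GridSpec-class].
#' @slot zones integer vector of zone codes (NA = masked).
#' @slot cvThreshold,richnessThreshold numeric thresholds that produced
#'   the map ("high" means strictly greater).
#' @slot nSpecies integer.
#' @exportClass ZoneMap
setClass("ZoneMap",
  representation(grid = "GridSpec", zones = "integer",
                 cvThreshold = "numeric", richnessThreshold = "numeric",
                 nSpecies = "integer"),
  validity = function(object) {
    if (length(object@zones) != object@grid@nRows * object@grid@nCols)
      return("zones length must match the grid")
    z <- object@zones[!is.na(object@zones)]
    if (length(z) && (any(z < 1L) || any(z > 6L)))
      return("zone codes must lie in 1..6")
    TRUE
  })

#' Sampling-effort ignorance map
#'
#' Half-ignorance index `h / (n + h)` of the per-cell record count `n`
#' of the reference grouping: 1 where no records exist, 0.5 at the
#' half-saturation count `h`.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric, raw index in (0, 1].
#' @slot rescaled numeric, the same map min-max rescaled to [0, 1].
#' @slot halfSaturation numeric.
#' @slot grouping character, reference grouping used (e.g. "family,
#'   pooled").
#' @exportClass IgnoranceMap
setClass("IgnoranceMap",
  representation(grid = "GridSpec", values = "numeric",
                 rescaled = "numeric", halfSaturation = "numeric",
                 grouping = "character"))
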