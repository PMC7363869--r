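checkRecords <- function(records) {
  need <- c("species", "decimalLongitude", "decimalLatitude",
            "coordinateUncertaintyInMeters", "basisOfRecord")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  records
}

#' Filter occurrence records by observation type and precision
#'
#' Keeps only georeferenced human or machine observations. Under the
#' `certain` variant, the coordinate uncertainty must be known and at
#' most `maxUncertaintyM` (inclusive); under `certain_plus_NA`, records
#' with missing uncertainty are kept as well. The default threshold of
#' 15,000 m matches the circumradius of a 0.25 degree (c. 30 km) cell.
#' Record order is preserved.
#'
#' @param records occurrence data.frame (see [sampleOccurrences()]).
#' @param variant `"certain"` or `"certain_plus_NA"`.
#' @param maxUncertaintyM inclusive uncertainty threshold in metres.
#' @return the filtered data.frame.
#' @export
filterRecords <- function(records,
                          variant = c("certain", "certain_plus_NA"),
                          maxUncertaintyM = 15000) {
  variant <- match.arg(variant)
  checkRecords(records)
  lon <- records$decimalLongitude
  lat <- records$decimalLatitude
  geo <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  basis <- records$basisOfRecord %in%
    c("human_observation", "machine_observation")
  unc <- records$coordinateUncertaintyInMeters
  prec <- if (variant == "certain") !is.na(unc) & unc <= maxUncertaintyM
          else is.na(unc) | unc <= maxUncertaintyM
  out <- records[geo & basis & prec, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove common coordinate errors
#'
#' Drops records with zero coordinates `(0, 0)`, records whose longitude
#' exactly equals their latitude, exact duplicates (same species and
#' coordinates; the first occurrence survives), and records within a
#' configured radius of any exclusion point (a generic stand-in for
#' country-centroid / institution gazetteers, empty by default).
#'
#' @param records occurrence data.frame.
#' @param exclusionPoints optional data.frame with columns `lon`, `lat`,
#'   `radiusM`.
#' @return the cleaned data.frame, order preserved.
#' @export
cleanCoordinates <- function(records, exclusionPoints = NULL) {
  checkRecords(records)
  lon <- records$decimalLongitude
  lat <- records$decimalLatitude
  drop <- (lon == 0 & lat == 0) | (lon == lat)
  drop <- drop | duplicated(records[, c("species", "decimalLongitude",
                                        "decimalLatitude")])
  if (!is.null(exclusionPoints) && nrow(exclusionPoints)) {
    for (k in seq_len(nrow(exclusionPoints))) {
      d <- geosphere::distHaversine(
        cbind(lon, lat),
        c(exclusionPoints$lon[k], exclusionPoints$lat[k]))
      drop <- drop | d <= exclusionPoints$radiusM[k]
    }
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Thin records to one presence per grid cell
#'
#' Records are assigned to grid cells with the half-open convention of
#' [pointToCell()]; each occupied in-extent cell contributes one
#' presence, and out-of-extent records are dropped and counted in the
#' provenance ledger.
#'
#' @param records cleaned occurrence data.frame.
#' @param grid a [GridSpec-class].
#' @param variant dataset variant label stored on the result.
#' @param nRaw,nAfterFilters,nAfterCleaning provenance counts carried
#'   from the earlier stages; default to `nrow(records)`.
#' @return a [SpeciesOccurrenceSet-class].
#' @export
thinToGrid <- function(records, grid,
                       variant = c("certain", "certain_plus_NA"),
                       nRaw = nrow(records),
                       nAfterFilters = nrow(records),
                       nAfterCleaning = nrow(records)) {
  variant <- match.arg(variant)
  checkRecords(records)
  species <- if (nrow(records)) records$species[1] else "unknown"
  cells <- if (nrow(records))
    pointToCell(grid, records$decimalLongitude, records$decimalLatitude)
  else integer()
  outside <- sum(is.na(cells))
  pres <- sort(unique(cells[!is.na(cells)]))
  new("SpeciesOccurrenceSet", species = species, variant = variant,
      grid = grid, presenceCells = as.integer(pres),
      nRaw = as.integer(nRaw), nAfterFilters = as.integer(nAfterFilters),
      nAfterCleaning = as.integer(nAfterCleaning),
      nOutside = as.integer(outside))
}

#' Run the full filter / clean / thin pipeline for one species
#'
#' @param records raw occurrence data.frame for a single species.
#' @param grid a [GridSpec-class].
#' @param variant `"certain"` or `"certain_plus_NA"`.
#' @param maxUncertaintyM inclusive precision threshold (metres).
#' @param exclusionPoints see [cleanCoordinates()].
#' @return a [SpeciesOccurrenceSet-class] with the full provenance
#'   ledger.
#' @export
prepareOccurrences <- function(records, grid,
                               variant = c("certain", "certain_plus_NA"),
                               maxUncertaintyM = 15000,
                               exclusionPoints = NULL) {
  variant <- match.arg(variant)
  nRaw <- nrow(records)
  filt <- filterRecords(records, variant, maxUncertaintyM)
  clean <- cleanCoordinates(filt, exclusionPoints)
  thinToGrid(clean, grid, variant, nRaw = nRaw,
             nAfterFilters = nrow(filt), nAfterCleaning = nrow(clean))
}

#' @describeIn prepareOccurrences presence cell indices of a set.
#' @param x a [SpeciesOccurrenceSet-class].
#' @export
presenceCells <- function(x) x@presenceCells

#' @describeIn prepareOccurrences provenance ledger as a one-row
#'   data.frame.
#' @export
provenanceLedger <- function(x) {
  data.frame(species = x@species, variant = x@variant, nRaw = x@nRaw,
             nAfterFilters = x@nAfterFilters,
             nAfterCleaning = x@nAfterCleaning,
             nOutside = x@nOutside,
             nAfterThinning = length(x@presenceCells))
}

setMethod("show", "SpeciesOccurrenceSet", function(object) {
  cat(sprintf(
    "SpeciesOccurrenceSet '%s' (%s): %d presence cells (raw %d -> filtered %d -> cleaned %d)\n",
    object@species, object@variant, length(object@presenceCells),
    object@nRaw, object@nAfterFilters, object@nAfterCleaning))
})
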