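#' Zone code table
#'
#' Integer codes, letters and labels of the six priority-management
#' zones.
#' @return a data.frame with columns `code`, `letter`, `label`.
#' @export
zoneLegend <- function() {
  data.frame(
    code = 1:6, letter = c("A", "B", "C", "D", "E", "F"),
    label = c("coldspot", "hotspot", "uncertain_coldspot",
              "uncertain_climatic_hotspot",
              "uncertain_environmental_hotspot", "uncertain_hotspot"),
    stringsAsFactors = FALSE)
}

#' Stack per-species binary maps into a richness map
#'
#' Per-cell sum of the species' binary predictions: the number of
#' species for which the cell is predicted suitable. A cell is nodata
#' only where every species map is nodata.
#'
#' @param binaries list of [RasterLayer-class] in \{0, 1\} on one grid.
#' @param name layer name.
#' @return a [RasterLayer-class] of integer richness.
#' @export
stackRichness <- function(binaries, name = "richness") {
  checkSharedGrid(binaries)
  M <- vapply(binaries, layerValues,
              numeric(nCells(binaries[[1]]@grid)))
  M <- matrix(M, nrow = nCells(binaries[[1]]@grid))
  bad <- M[!is.na(M)]
  if (length(bad) && any(bad != 0 & bad != 1))
    stop("binary layers must contain only 0/1 values")
  anyValid <- rowSums(!is.na(M)) > 0
  r <- rowSums(M, na.rm = TRUE)
  r[!anyValid] <- NA_real_
  rasterLayer(binaries[[1]]@grid, r, name)
}

#' Average per-species CV maps
#'
#' Per-cell arithmetic mean over the species with a valid value.
#'
#' @param cvLayers list of [RasterLayer-class] on one grid.
#' @param name layer name.
#' @return a [RasterLayer-class].
#' @export
meanCvMap <- function(cvLayers, name = "mean_cv") {
  checkSharedGrid(cvLayers)
  M <- vapply(cvLayers, layerValues,
              numeric(nCells(cvLayers[[1]]@grid)))
  M <- matrix(M, nrow = nCells(cvLayers[[1]]@grid))
  rasterLayer(cvLayers[[1]]@grid, rowMeans(M, na.rm = TRUE), name)
}

checkSharedGrid <- function(layers) {
  if (!length(layers)) stop("need at least one layer")
  g <- layers[[1]]@grid
  for (l in layers) if (!identical(l@grid, g))
    stop("layers do not share one grid")
  invisible(g)
}

#' Classify grid cells into priority-management zones
#'
#' The classification tree splits each cell on prediction agreement
#' first, then on predicted richness. "High" means strictly greater
#' than the threshold, so the central values themselves fall in "low".
#' Certain cells (CV low): regional richness high gives B (hotspot),
#' otherwise A (coldspot). Uncertain cells (CV high): regional and
#' global richness both high gives F (uncertain hotspot), both low C
#' (uncertain coldspot), regional high / global low E (uncertain
#' environmental hotspot), regional low / global high D (uncertain
#' climatic hotspot). Cells that are nodata in any input are masked.
#'
#' @param meanCv a [RasterLayer-class], mean CV of the regional
#'   ensembles over species, in [0, 1].
#' @param regionalRichness,globalRichness [RasterLayer-class] richness
#'   maps on the same grid.
#' @param cvThreshold CV split (default 0.5, the central value of
#'   [0, 1]).
#' @param richnessThreshold richness split; default
#'   `floor(nSpecies / 2)`, the central value of `0..nSpecies` (7 for
#'   15 species).
#' @param nSpecies species count; default the maximum observed richness.
#' @return a [ZoneMap-class].
#' @export
classifyZones <- function(meanCv, regionalRichness, globalRichness,
                          cvThreshold = 0.5, richnessThreshold = NULL,
                          nSpecies = NULL) {
  checkSharedGrid(list(meanCv, regionalRichness, globalRichness))
  if (is.null(nSpecies))
    nSpecies <- max(c(regionalRichness@values, globalRichness@values),
                    na.rm = TRUE)
  if (is.null(richnessThreshold))
    richnessThreshold <- floor(nSpecies / 2)
  cv <- meanCv@values
  rr <- regionalRichness@values
  gr <- globalRichness@values
  z <- rep(NA_integer_, length(cv))
  ok <- !is.na(cv) & !is.na(rr) & !is.na(gr)
  certain <- ok & cv <= cvThreshold
  rHigh <- rr > richnessThreshold
  gHigh <- gr > richnessThreshold
  z[certain & !rHigh] <- 1L                     # A coldspot
  z[certain & rHigh] <- 2L                      # B hotspot
  uncertain <- ok & cv > cvThreshold
  z[uncertain & !rHigh & !gHigh] <- 3L          # C uncertain coldspot
  z[uncertain & !rHigh & gHigh] <- 4L           # D uncertain climatic hotspot
  z[uncertain & rHigh & !gHigh] <- 5L           # E uncertain environmental
  z[uncertain & rHigh & gHigh] <- 6L            # F uncertain hotspot
  new("ZoneMap", grid = meanCv@grid, zones = z,
      cvThreshold = cvThreshold,
      richnessThreshold = as.numeric(richnessThreshold),
      nSpecies = as.integer(nSpecies))
}

#' @describeIn classifyZones zone codes as a [RasterLayer-class].
#' @param zoneMap a [ZoneMap-class].
#' @export
zoneLayer <- function(zoneMap) {
  rasterLayer(zoneMap@grid, as.numeric(zoneMap@zones), "zones")
}

#' Per-zone summary statistics
#'
#' For every zone A-F: the fraction of valid (non-masked) cells it
#' covers and the mean/min/max of each supplied layer over its cells.
#' Zones with no cells report 0 cells and `NA` statistics.
#'
#' @param zoneMap a [ZoneMap-class].
#' @param layers named list of [RasterLayer-class] on the same grid
#'   (e.g. MESS proportion, ignorance, mean CV).
#' @return a data.frame, one row per zone.
#' @export
zoneStatistics <- function(zoneMap, layers = list()) {
  if (length(layers)) checkSharedGrid(c(list(zoneLayer(zoneMap)), layers))
  z <- zoneMap@zones
  nValid <- sum(!is.na(z))
  leg <- zoneLegend()
  out <- lapply(leg$code, function(code) {
    cells <- which(!is.na(z) & z == code)
    row <- data.frame(zone = leg$letter[code], label = leg$label[code],
                      nCells = length(cells),
                      fraction = if (nValid) length(cells) / nValid else 0,
                      stringsAsFactors = FALSE)
    for (nm in names(layers)) {
      v <- layers[[nm]]@values[cells]
      v <- v[!is.na(v)]
      row[[paste0(nm, "Mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(nm, "Min")]] <- if (length(v)) min(v) else NA_real_
      row[[paste0(nm, "Max")]] <- if (length(v)) max(v) else NA_real_
    }
    row
  })
  do.call(rbind, out)
}

setMethod("show", "ZoneMap", function(object) {
  tab <- table(factor(object@zones, levels = 1:6,
                      labels = zoneLegend()$letter))
  cat(sprintf(
    "ZoneMap (%d species, CV > %g / richness > %g): %s; %d masked\n",
    object@nSpecies, object@cvThreshold, object@richnessThreshold,
    paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
    sum(is.na(object@zones))))
})
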