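#' Virtual species configuration
#'
#' Convenience constructor for [VirtualSpeciesConfig-class]. Defaults
#' place the log-normal coordinate uncertainty at log-mean `log(5000)` m
#' with log-sd 1, so a realistic tail of records exceeds the 15,000 m
#' precision filter in both directions.
#'
#' @param speciesName,family character labels (family is the reference
#'   group used by ignorance maps).
#' @param linearCoefficients named numeric, linear terms per predictor
#'   layer.
#' @param quadraticCoefficients named numeric, optional squared terms.
#' @param intercept numeric; ignored when `prevalenceTarget` is set.
#' @param prevalenceTarget target mean suitability in (0, 1), or `NA`.
#' @param nRecords number of presence-only records to draw.
#' @param biasLayerName layer name used as a sampling-bias surface, or
#'   `NA` for unbiased sampling.
#' @param pMissingUncertainty fraction of records whose coordinate
#'   uncertainty is missing.
#' @param uncertaintyLogMean,uncertaintyLogSd log-normal parameters of
#'   coordinate uncertainty (metres).
#' @param pErrorRecords fraction of records corrupted into one of the
#'   three cleanable error classes (zero coordinates, lon set equal to
#'   lat, exact duplicate of an earlier record).
#' @param seed integer.
#' @return a [VirtualSpeciesConfig-class].
#' @export
virtualSpeciesConfig <- function(speciesName, linearCoefficients,
                                 quadraticCoefficients = numeric(),
                                 intercept = 0,
                                 prevalenceTarget = NA_real_,
                                 nRecords = 500L,
                                 biasLayerName = NA_character_,
                                 pMissingUncertainty = 0.3,
                                 uncertaintyLogMean = log(5000),
                                 uncertaintyLogSd = 1,
                                 pErrorRecords = 0.05,
                                 family = "Synthetica",
                                 seed = 1L) {
  new("VirtualSpeciesConfig", speciesName = speciesName, family = family,
      linearCoefficients = linearCoefficients,
      quadraticCoefficients = quadraticCoefficients,
      intercept = as.numeric(intercept),
      prevalenceTarget = as.numeric(prevalenceTarget),
      nRecords = as.integer(nRecords),
      biasLayerName = biasLayerName,
      pMissingUncertainty = as.numeric(pMissingUncertainty),
      uncertaintyLogMean = as.numeric(uncertaintyLogMean),
      uncertaintyLogSd = as.numeric(uncertaintyLogSd),
      pErrorRecords = as.numeric(pErrorRecords), seed = as.integer(seed))
}

#' Generate a synthetic environmental raster stack
#'
#' Smoothed Gaussian random fields standing in for climatic variables
#' and general habitat descriptors. Each base layer is white noise
#' smoothed with a truncated Gaussian kernel of standard deviation
#' `autocorrRangeCells` (0 = no smoothing) and standardized to mean 0,
#' sd 1 over valid cells. `duplicatePairs` additional layers are
#' near-copies (correlation > 0.99) of existing layers, named
#' `<base>_dup`, to give collinearity screening real work. Layer names
#' carry a `climate`/`habitat` prefix.
#'
#' @param grid a [GridSpec-class].
#' @param nClimate,nHabitat numbers of base layers (each >= 1).
#' @param autocorrRangeCells smoothing range in cells (>= 0).
#' @param duplicatePairs number of near-duplicate layers to append.
#' @param seed integer.
#' @return a [RasterStack-class] with `nClimate + nHabitat +
#'   duplicatePairs` layers.
#' @export
generateEnvironment <- function(grid, nClimate = 3L, nHabitat = 2L,
                                autocorrRangeCells = 4,
                                duplicatePairs = 0L, seed = 1L) {
  stopifnot(nClimate >= 1, nHabitat >= 1, autocorrRangeCells >= 0)
  if (autocorrRangeCells > 0 &&
      2 * ceiling(3 * autocorrRangeCells) + 1 > min(grid@nRows, grid@nCols))
    stop("grid too small for the requested smoothing range")
  set.seed(seed)
  Wr <- smoothingKernel(grid@nRows, autocorrRangeCells)
  Wc <- smoothingKernel(grid@nCols, autocorrRangeCells)
  baseNames <- c(paste0("climate", seq_len(nClimate)),
                 paste0("habitat", seq_len(nHabitat)))
  layers <- lapply(baseNames, function(nm) {
    noise <- matrix(stats::rnorm(nCells(grid)), nrow = grid@nRows,
                    ncol = grid@nCols, byrow = TRUE)
    sm <- Wr %*% noise %*% t(Wc)
    v <- as.numeric(t(sm))             # back to linear cell order
    rasterLayer(grid, standardize(v), name = nm)
  })
  names(layers) <- baseNames
  if (duplicatePairs > 0) {
    src <- rep_len(baseNames, duplicatePairs)
    for (i in seq_len(duplicatePairs)) {
      v <- layers[[src[i]]]@values +
        stats::rnorm(nCells(grid), sd = 0.05)
      nm <- paste0(src[i], "_dup", if (duplicatePairs > length(baseNames))
        i else "")
      layers[[nm]] <- rasterLayer(grid, standardize(v), name = nm)
    }
  }
  rasterStack(layers)
}

smoothingKernel <- function(n, range) {
  if (range <= 0) return(diag(n))
  h <- ceiling(3 * range)
  d <- outer(seq_len(n), seq_len(n), "-")
  W <- exp(-d^2 / (2 * range^2)) * (abs(d) <= h)
  W / rowSums(W)
}

standardize <- function(v) {
  mu <- mean(v, na.rm = TRUE)
  sdv <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) stop("degenerate layer: zero variance")
  (v - mu) / sdv
}

#' Ground-truth suitability surface of a virtual species
#'
#' Per-cell `plogis(intercept + sum(beta x) + sum(gamma x^2))` over the
#' named predictor layers. When the configuration carries a prevalence
#' target, the intercept is re-solved by bisection so the mean
#' suitability over valid cells matches the target within 0.005; the
#' solved intercept is attached as attribute `intercept`.
#'
#' @param stack a [RasterStack-class] holding every named predictor.
#' @param cfg a [VirtualSpeciesConfig-class].
#' @return a [RasterLayer-class] with values in (0, 1).
#' @export
trueSuitability <- function(stack, cfg) {
  need <- unique(c(names(cfg@linearCoefficients),
                   names(cfg@quadraticCoefficients)))
  missing <- setdiff(need, layerNames(stack))
  if (length(missing))
    stop("unknown predictor name(s): ", paste(missing, collapse = ", "))
  X <- stackValues(stack)
  eta <- rep(0, nrow(X))
  for (nm in names(cfg@linearCoefficients))
    eta <- eta + cfg@linearCoefficients[[nm]] * X[, nm]
  for (nm in names(cfg@quadraticCoefficients))
    eta <- eta + cfg@quadraticCoefficients[[nm]] * X[, nm]^2
  b0 <- cfg@intercept
  if (is.finite(cfg@prevalenceTarget)) {
    target <- cfg@prevalenceTarget
    f <- function(b) mean(stats::plogis(b + eta), na.rm = TRUE) - target
    lo <- -60; hi <- 60
    for (i in 1:200) {
      b0 <- (lo + hi) / 2
      if (abs(f(b0)) < 1e-4) break
      if (f(b0) > 0) hi <- b0 else lo <- b0
    }
  }
  out <- stats::plogis(b0 + eta)
  layer <- rasterLayer(stack@grid, out,
                       name = paste0("truth_", cfg@speciesName))
  attr(layer, "intercept") <- b0
  layer
}

#' Sample presence-only occurrence records from a suitability surface
#'
#' Cells are drawn with replacement with probability proportional to
#' `truth * bias` (bias 1 when absent), one uniform point is placed
#' inside each drawn cell, and the record is annotated the way
#' opportunistic biodiversity-portal data arrive: log-normal coordinate
#' uncertainty in metres (missing with probability
#' `pMissingUncertainty`), a basis-of-record label, and — with
#' probability `pErrorRecords` — corruption into one of three common
#' coordinate errors (zero coordinates, longitude set equal to
#' latitude, exact duplicate of an earlier record). The injected error
#' class is recorded in the `rawFlag` column, which the cleaning
#' pipeline never reads; it exists for validation only.
#'
#' @param truth a [RasterLayer-class] with values in [0, 1].
#' @param cfg a [VirtualSpeciesConfig-class].
#' @param bias optional [RasterLayer-class] of nonnegative sampling
#'   effort.
#' @return a data.frame with Darwin-Core-like columns `species`,
#'   `decimalLongitude`, `decimalLatitude`,
#'   `coordinateUncertaintyInMeters`, `basisOfRecord`, `family`,
#'   `rawFlag`.
#' @export
sampleOccurrences <- function(truth, cfg, bias = NULL) {
  v <- truth@values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("truth values must lie in [0, 1]")
  p <- ifelse(is.na(v), 0, v)
  if (!is.null(bias)) {
    b <- bias@values
    if (any(b < 0, na.rm = TRUE)) stop("bias values must be nonnegative")
    p <- p * ifelse(is.na(b), 0, b)
  }
  if (sum(p) <= 0)
    stop("no suitable habitat: suitability (times bias) is zero everywhere")
  set.seed(cfg@seed)
  n <- cfg@nRecords
  grid <- truth@grid
  cells <- sample.int(nCells(grid), n, replace = TRUE, prob = p)
  rc <- cellRowCol(grid, cells)
  lon <- grid@minLon + (rc$col - 1 + stats::runif(n)) * grid@cellSize
  lat <- grid@minLat + (rc$row - 1 + stats::runif(n)) * grid@cellSize
  unc <- stats::rlnorm(n, cfg@uncertaintyLogMean, cfg@uncertaintyLogSd)
  unc[stats::runif(n) < cfg@pMissingUncertainty] <- NA_real_
  basis <- sample(c("human_observation", "machine_observation"), n,
                  replace = TRUE, prob = c(0.85, 0.15))
  flag <- rep("", n)
  corrupt <- which(stats::runif(n) < cfg@pErrorRecords)
  for (i in corrupt) {
    type <- sample(c("zero_coordinates", "lon_equals_lat", "duplicate"), 1)
    if (type == "duplicate" && i == 1) type <- "zero_coordinates"
    if (type == "zero_coordinates") {
      lon[i] <- 0; lat[i] <- 0
    } else if (type == "lon_equals_lat") {
      lon[i] <- lat[i]
    } else {
      j <- sample.int(i - 1, 1)
      lon[i] <- lon[j]; lat[i] <- lat[j]
    }
    flag[i] <- type
  }
  data.frame(species = cfg@speciesName, decimalLongitude = lon,
             decimalLatitude = lat, coordinateUncertaintyInMeters = unc,
             basisOfRecord = basis, family = cfg@family, rawFlag = flag,
             stringsAsFactors = FALSE)
}

#' Read and write occurrence tables
#'
#' CSV with the Darwin-Core-like header used across the pipeline
#' (`species`, `decimalLongitude`, `decimalLatitude`,
#' `coordinateUncertaintyInMeters`, `basisOfRecord`, plus optional
#' `family` and `rawFlag` columns).
#'
#' @param records a data.frame as produced by [sampleOccurrences()].
#' @param path CSV file path.
#' @return `readOccurrences` returns the data.frame; `writeOccurrences`
#'   returns `path` invisibly.
#' @export
writeOccurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOccurrences
#' @export
readOccurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "decimalLongitude", "decimalLatitude",
            "coordinateUncertaintyInMeters", "basisOfRecord")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence file lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}
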