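#' Multivariate environmental similarity surface (MESS)
#'
#' For each variable, with `p` the percentage of reference values
#' strictly below the target value: similarity is
#' `(value - min) / (max - min) * 100` when `p = 0`, `2p` when
#' `p <= 50`, `2(100 - p)` when `50 < p < 100`, and
#' `(max - value) / (max - min) * 100` when `p = 100`. The cell's MESS
#' is the minimum similarity over variables; negative values flag
#' extrapolation beyond the reference (training) conditions. Variables
#' that are constant in the reference set are skipped with a warning.
#'
#' @param reference matrix or data.frame of predictor values at the
#'   reference (training) points; columns aligned by name with the
#'   stack.
#' @param targetStack a [RasterStack-class] of the same variables.
#' @return a [RasterLayer-class] of MESS values (nodata where any
#'   predictor is nodata).
#' @export
messLayer <- function(reference, targetStack) {
  reference <- as.matrix(reference)
  if (!nrow(reference)) stop("reference set is empty")
  vars <- intersect(colnames(reference), layerNames(targetStack))
  if (!length(vars))
    stop("no shared variables between reference and target stack")
  X <- stackValues(targetStack)[, vars, drop = FALSE]
  valid <- which(stats::complete.cases(X))
  sim <- matrix(NA_real_, nrow = length(valid), ncol = length(vars))
  used <- logical(length(vars))
  for (j in seq_along(vars)) {
    ref <- sort(reference[, vars[j]])
    lo <- ref[1]; hi <- ref[length(ref)]
    if (hi - lo <= 0) {
      warning("variable '", vars[j],
              "' is constant in the reference set; skipped")
      next
    }
    used[j] <- TRUE
    t <- X[valid, j]
    p <- 100 * findInterval(t, ref, left.open = TRUE) / length(ref)
    s <- numeric(length(t))
    i0 <- p == 0
    i100 <- p == 100
    iLow <- !i0 & p <= 50
    iHigh <- !i100 & p > 50
    s[i0] <- (t[i0] - lo) / (hi - lo) * 100
    s[i100] <- (hi - t[i100]) / (hi - lo) * 100
    s[iLow] <- 2 * p[iLow]
    s[iHigh] <- 2 * (100 - p[iHigh])
    sim[, j] <- s
  }
  if (!any(used)) stop("all reference variables are degenerate")
  v <- rep(NA_real_, nCells(targetStack@grid))
  v[valid] <- apply(sim[, used, drop = FALSE], 1, min)
  rasterLayer(targetStack@grid, v, "mess")
}

#' Proportion of species in dissimilar environments
#'
#' Per-cell fraction of species whose MESS is negative, over the
#' species with a valid MESS value at the cell.
#'
#' @param perSpeciesMess list of MESS [RasterLayer-class] on one grid.
#' @return a [RasterLayer-class] with values in [0, 1].
#' @export
messProportion <- function(perSpeciesMess) {
  checkSharedGrid(perSpeciesMess)
  M <- vapply(perSpeciesMess, layerValues,
              numeric(nCells(perSpeciesMess[[1]]@grid)))
  M <- matrix(M, nrow = nCells(perSpeciesMess[[1]]@grid))
  rasterLayer(perSpeciesMess[[1]]@grid, rowMeans(M < 0, na.rm = TRUE),
              "mess_proportion")
}

#' Sampling-effort ignorance map
#'
#' Half-ignorance index of the per-cell record count `n` of the
#' reference grouping: `h / (n + h)`, which is 1 where no records
#' exist, 0.5 at the half-saturation count `h`, and strictly decreasing
#' in `n`. Counts are pooled across reference groups by default; with
#' `perGroup = TRUE` a map per group is returned instead.
#'
#' @param records occurrence data.frame carrying a `family` column (the
#'   reference group).
#' @param grid a [GridSpec-class].
#' @param halfSaturation the record count at which ignorance is 0.5
#'   (default 1).
#' @param perGroup return a named list of per-group maps instead of the
#'   pooled map.
#' @return an [IgnoranceMap-class], or a named list of them.
#' @export
ignoranceMap <- function(records, grid, halfSaturation = 1,
                         perGroup = FALSE) {
  if (!"family" %in% names(records))
    records$family <- "all"
  makeMap <- function(recs, label) {
    n <- numeric(nCells(grid))
    if (nrow(recs)) {
      cells <- pointToCell(grid, recs$decimalLongitude,
                           recs$decimalLatitude)
      tab <- table(cells[!is.na(cells)])
      n[as.integer(names(tab))] <- as.numeric(tab)
    }
    v <- halfSaturation / (n + halfSaturation)
    rng <- range(v)
    resc <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0, length(v))
    new("IgnoranceMap", grid = grid, values = v, rescaled = resc,
        halfSaturation = halfSaturation, grouping = label)
  }
  if (perGroup) {
    groups <- split(records, records$family)
    lapply(groups, function(g) makeMap(g, paste0("family:", g$family[1])))
  } else {
    makeMap(records, "family, pooled")
  }
}

#' @describeIn ignoranceMap raw index values as a [RasterLayer-class].
#' @param x an [IgnoranceMap-class].
#' @param rescaled return the min-max rescaled map instead of the raw
#'   one.
#' @export
ignoranceLayer <- function(x, rescaled = FALSE) {
  rasterLayer(x@grid, if (rescaled) x@rescaled else x@values, "ignorance")
}

setMethod("show", "IgnoranceMap", function(object) {
  cat(sprintf(
    "IgnoranceMap (%s, h = %g): mean %.3f, %.1f%% of cells without records\n",
    object@grouping, object@halfSaturation, mean(object@values),
    100 * mean(object@values == 1)))
})

#' Bhattacharyya distance between two prediction maps
#'
#' The maps are normalized to sum 1 over their shared valid cells and
#' compared as distributions: `-log(sum(sqrt(p * q)))`, 0 iff the
#' normalized maps coincide, `Inf` for disjoint support.
#'
#' @param a,b [RasterLayer-class] with nonnegative values on one grid.
#' @return a nonnegative numeric (possibly `Inf`).
#' @export
bhattacharyyaDistance <- function(a, b) {
  checkSharedGrid(list(a, b))
  ok <- !is.na(a@values) & !is.na(b@values)
  p <- a@values[ok]; q <- b@values[ok]
  if (any(p < 0) || any(q < 0)) stop("maps must be nonnegative")
  if (sum(p) == 0 || sum(q) == 0)
    stop("cannot normalize an all-zero map")
  p <- p / sum(p); q <- q / sum(q)
  bc <- sum(sqrt(p * q))
  if (bc <= 0) Inf else max(0, -log(bc))
}
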