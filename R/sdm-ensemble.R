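#' Sample a pseudo-absence set
#'
#' Uniform sample without replacement from the valid cells of the region
#' mask, excluding presence cells; weights start at 1 (every
#' pseudo-absence initially counts as a full absence).
#'
#' @param regionMask a [RasterLayer-class]; candidate cells are those
#'   with a non-`NA`, nonzero value.
#' @param n number of pseudo-absences.
#' @param presenceCells integer cell indices never to sample.
#' @param seed integer.
#' @param id set identifier stored on the result.
#' @return a [PseudoAbsenceSet-class].
#' @export
samplePseudoAbsences <- function(regionMask, n, presenceCells = integer(),
                                 seed = 1L, id = 1L) {
  v <- regionMask@values
  candidates <- setdiff(which(!is.na(v) & v != 0), presenceCells)
  if (length(candidates) < n)
    stop(sprintf(
      "insufficient pseudo-absence candidates: %d requested, %d available",
      n, length(candidates)))
  set.seed(seed)
  cells <- if (length(candidates) == n) candidates
           else sample(candidates, n)
  new("PseudoAbsenceSet", id = as.integer(id), cells = as.integer(cells),
      weights = rep(1, n))
}

#' Weight pseudo-absences by a global climatic projection
#'
#' The reliability of a pseudo-absence falls with the global climatic
#' suitability `p` of its cell through the inverse-logistic weight
#' `Weight(p) = 1 / (1 + (p / (p - 1))^2)`, with `Weight(1) = 0`: a
#' pseudo-absence in climatically unsuitable terrain (`p = 0`) counts as
#' a full absence (weight 1), one in fully suitable terrain counts not
#' at all. The weight is strictly decreasing on (0, 1) and satisfies
#' `Weight(p) + Weight(1 - p) = 1`.
#'
#' @param pa a [PseudoAbsenceSet-class].
#' @param projG a [RasterLayer-class] of global suitability in [0, 1],
#'   defined at every pseudo-absence cell.
#' @return a re-weighted [PseudoAbsenceSet-class].
#' @export
weightPseudoAbsences <- function(pa, projG) {
  p <- projG@values[pa@cells]
  if (anyNA(p))
    stop("global projection undefined at some pseudo-absence cells")
  if (any(p < -1e-12 | p > 1 + 1e-12))
    stop("global projection values must lie in [0, 1]")
  p <- clamp01(p)
  w <- ifelse(p >= 1, 0, 1 / (1 + (p / (p - 1))^2))
  new("PseudoAbsenceSet", id = pa@id, cells = pa@cells, weights = w)
}

#' Split presences and pseudo-absences into training and evaluation sets
#'
#' Class-stratified random split: the fraction applies independently to
#' presences and pseudo-absences, reliability weights travel with their
#' pseudo-absences, and the two parts are disjoint and exhaustive.
#'
#' @param presenceCells integer cell indices (>= 10).
#' @param pa a [PseudoAbsenceSet-class].
#' @param fraction training share (default 0.7).
#' @param seed integer.
#' @return a list with elements `train` and `eval`, each a list of
#'   `presences`, `paCells`, `paWeights`.
#' @export
splitTrainEval <- function(presenceCells, pa, fraction = 0.7, seed = 1L) {
  nP <- length(presenceCells)
  if (nP < 10) stop("too few presences to split (need >= 10)")
  nA <- length(pa@cells)
  set.seed(seed)
  trP <- sample.int(nP, round(fraction * nP))
  trA <- sample.int(nA, round(fraction * nA))
  list(train = list(presences = presenceCells[trP],
                    paCells = pa@cells[trA], paWeights = pa@weights[trA]),
       eval = list(presences = presenceCells[-trP],
                   paCells = pa@cells[-trA], paWeights = pa@weights[-trA]))
}

#' Threshold-optimized binary classification metrics
#'
#' Scans the cutoff lattice, classifying `scores >= cutoff` as presence,
#' and returns sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)` and `TSS = sensitivity + specificity - 1` at the
#' TSS-maximizing cutoff (ties take the smallest cutoff).
#'
#' @param scores numeric in [0, 1].
#' @param labels binary (0/1) of the same length, both classes present.
#' @param cutoffLattice numeric cutoffs to scan (default 0, 0.01, .., 1).
#' @return a list with `sensitivity`, `specificity`, `tss`, `cutoff`.
#' @export
evaluateBinary <- function(scores, labels,
                           cutoffLattice = seq(0, 1, by = 0.01)) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels contain NA")
  pos <- labels == 1
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to evaluate")
  sens <- vapply(cutoffLattice,
                 function(co) sum(scores[pos] >= co) / nPos, numeric(1))
  spec <- vapply(cutoffLattice,
                 function(co) sum(scores[!pos] < co) / nNeg, numeric(1))
  tss <- sens + spec - 1
  best <- which(tss >= max(tss) - 1e-12)[1]
  list(sensitivity = sens[best], specificity = spec[best],
       tss = tss[best], cutoff = cutoffLattice[best])
}

#' Select skilled ensemble members
#'
#' Members with held-out TSS at or above `tssMin`; when none qualifies,
#' the `ceiling(fallbackQuantile * N)` highest-TSS members (stable order
#' on ties) so the ensemble is never empty.
#'
#' @param members list of [FittedMember-class].
#' @param tssMin selection threshold (default 0.7).
#' @param fallbackQuantile top fraction kept as fallback (default 0.1).
#' @return a non-empty list of members.
#' @export
selectMembers <- function(members, tssMin = 0.7, fallbackQuantile = 0.1) {
  if (!length(members)) stop("no members to select from")
  tss <- vapply(members, function(m) m@evalTss, numeric(1))
  keep <- tss >= tssMin
  if (any(keep)) return(members[keep])
  k <- ceiling(fallbackQuantile * length(members))
  members[order(-tss)[seq_len(k)]]
}

#' Committee average and coefficient of variation
#'
#' Each member's continuous prediction is binarized at its own member
#' cutoff; the committee suitability is the per-cell mean of those
#' binaries (the fraction of members voting presence) and the
#' uncertainty map is their per-cell coefficient of variation
#' (population sd / mean, 0 where the mean is 0), standardized to
#' [0, 1] by the maximum finite value on the map.
#'
#' @param members non-empty list of [FittedMember-class].
#' @param X predictor matrix, one row per grid cell.
#' @param grid the [GridSpec-class] of the map.
#' @param validCells integer indices of cells to predict (complete
#'   predictor rows).
#' @return a list of two [RasterLayer-class]: `suitability`, `cv`.
#' @export
committeeAverage <- function(members, X, grid, validCells) {
  if (!length(members)) stop("committeeAverage needs >= 1 member")
  Xv <- X[validCells, , drop = FALSE]
  B <- vapply(members, function(m)
    as.numeric(predictMember(m, Xv) >= m@memberCutoff),
    numeric(length(validCells)))
  comm <- committeeFromBinaries(matrix(B, nrow = length(validCells)))
  suit <- rep(NA_real_, nCells(grid)); suit[validCells] <- comm$mean
  cvv <- rep(NA_real_, nCells(grid)); cvv[validCells] <- comm$cv
  list(suitability = rasterLayer(grid, suit, "committee_suitability"),
       cv = rasterLayer(grid, cvv, "committee_cv"))
}

# committee mean and standardized CV from a cells x members 0/1 matrix
committeeFromBinaries <- function(B) {
  m <- rowMeans(B)
  sdPop <- sqrt(pmax(rowMeans(B^2) - m^2, 0))
  cv <- ifelse(m == 0, 0, sdPop / m)
  mx <- max(cv[is.finite(cv)], 0)
  if (mx > 0) cv <- cv / mx
  list(mean = m, cv = cv)
}

#' Binarize an ensemble suitability map
#'
#' The ensemble cutoff is the TSS-maximizing lattice value against the
#' supplied presence and pseudo-absence cells; the binary map is
#' `suitability >= cutoff`.
#'
#' @param suitability a [RasterLayer-class] in [0, 1].
#' @param presenceCells,paCells integer cell indices with valid
#'   suitability values.
#' @param cutoffLattice cutoffs to scan.
#' @return a list with `binary` ([RasterLayer-class]), `cutoff`, `tss`,
#'   `sensitivity`, `specificity`.
#' @export
binarizeEnsemble <- function(suitability, presenceCells, paCells,
                             cutoffLattice = seq(0, 1, by = 0.01)) {
  s <- suitability@values
  scores <- c(s[presenceCells], s[paCells])
  labels <- c(rep(1, length(presenceCells)), rep(0, length(paCells)))
  ok <- !is.na(scores)
  ev <- evaluateBinary(scores[ok], labels[ok], cutoffLattice)
  b <- ifelse(is.na(s), NA_real_, as.numeric(s >= ev$cutoff))
  list(binary = rasterLayer(suitability@grid, b, "binary"),
       cutoff = ev$cutoff, tss = ev$tss, sensitivity = ev$sensitivity,
       specificity = ev$specificity)
}

#' Range filling of a binary prediction
#'
#' Fraction of the cells classified as presence that hold observed
#' presence records — a proxy for how close the species is to filling
#' its predicted suitable range. `NA` (undefined) when no cell is
#' predicted present.
#'
#' @param binary a [RasterLayer-class] in \{0, 1\}.
#' @param presenceCells integer cell indices of observed presences.
#' @return a fraction in [0, 1], or `NA_real_`.
#' @export
rangeFilling <- function(binary, presenceCells) {
  predicted <- which(!is.na(binary@values) & binary@values == 1)
  if (!length(predicted)) {
    warning("empty predicted range: range filling undefined")
    return(NA_real_)
  }
  length(intersect(predicted, presenceCells)) / length(predicted)
}

#' Fit a committee-averaging ensemble for one species and tier
#'
#' Runs the full member factory (`nPaSets` pseudo-absence sets x
#' `nCvRuns` 70/30 splits x the learner roster), selects skilled
#' members, committee-averages them, optimizes the ensemble cutoff
#' against the full presence/pseudo-absence data, and assembles the
#' metrics reported per species: TSS, sensitivity, specificity, binary
#' cutoff, mean CV and range filling. When `projG` is supplied the
#' pseudo-absences are reliability-weighted by
#' [weightPseudoAbsences()]; without it they are unweighted (the global
#' tier).
#'
#' @param presenceCells integer presence cell indices.
#' @param stack predictor [RasterStack-class].
#' @param config an [ensembleConfig()].
#' @param seed master seed of this ensemble; child seeds per
#'   pseudo-absence set and split derive from it via [childSeed()].
#' @param projG optional [RasterLayer-class] of global suitability used
#'   to weight pseudo-absences.
#' @param tier label stored on the result.
#' @return an [EnsemblePrediction-class].
#' @export
fitEnsemble <- function(presenceCells, stack, config = ensembleConfig(),
                        seed = 1L, projG = NULL, tier = "unspecified") {
  X <- stackValues(stack)
  grid <- stack@grid
  valid <- which(stats::complete.cases(X))
  drop <- setdiff(presenceCells, valid)
  if (length(drop)) {
    warning(sprintf("%d presence cell(s) without predictor values dropped",
                    length(drop)))
    presenceCells <- intersect(presenceCells, valid)
  }
  mask <- rasterLayer(grid, {
    v <- rep(NA_real_, nCells(grid)); v[valid] <- 1; v
  }, "mask")
  members <- list()
  memberRows <- list()
  paCellsAll <- integer()
  for (s in seq_len(config$nPaSets)) {
    pa <- samplePseudoAbsences(mask, config$nPseudoAbsences,
                               presenceCells,
                               seed = childSeed(seed, "pa", s), id = s)
    if (!is.null(projG)) pa <- weightPseudoAbsences(pa, projG)
    if (sum(pa@weights) == 0)
      warning(sprintf(
        "pseudo-absence set %d: all weights are zero (projG = 1 over the region); members see a presence-only signal",
        s))
    paCellsAll <- union(paCellsAll, pa@cells)
    for (r in seq_len(config$nCvRuns)) {
      sp <- splitTrainEval(presenceCells, pa, config$trainFraction,
                           seed = childSeed(seed, "split", s, r))
      for (alg in config$algorithms) {
        m <- tryCatch(
          suppressWarnings(fitMember(alg, X, sp$train, sp$eval,
                                     params = config, paSetId = s,
                                     cvRunId = r)),
          error = function(e) {
            warning(sprintf("member %s (set %d, run %d) failed: %s",
                            alg, s, r, conditionMessage(e)))
            NULL
          })
        if (!is.null(m)) {
          members[[length(members) + 1L]] <- m
          memberRows[[length(memberRows) + 1L]] <- data.frame(
            algorithm = alg, paSet = s, cvRun = r,
            evalTss = m@evalTss, evalSensitivity = m@evalSensitivity,
            evalSpecificity = m@evalSpecificity,
            memberCutoff = m@memberCutoff, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(members)) stop("all ensemble members failed to fit")
  selected <- selectMembers(members, config$tssMin,
                            config$fallbackQuantile)
  comm <- committeeAverage(selected, X, grid, valid)
  lattice <- seq(0, 1, by = config$cutoffStep)
  bin <- binarizeEnsemble(comm$suitability, presenceCells, paCellsAll,
                          lattice)
  memberTable <- do.call(rbind, memberRows)
  memberTable$selected <- vapply(seq_len(nrow(memberTable)), function(i) {
    any(vapply(selected, function(m)
      m@algorithm == memberTable$algorithm[i] &&
        m@paSetId == memberTable$paSet[i] &&
        m@cvRunId == memberTable$cvRun[i], logical(1)))
  }, logical(1))
  new("EnsemblePrediction", tier = tier, suitability = comm$suitability,
      cv = comm$cv, binary = bin$binary, cutoff = bin$cutoff,
      tss = bin$tss, sensitivity = bin$sensitivity,
      specificity = bin$specificity,
      meanCv = mean(comm$cv@values, na.rm = TRUE),
      rangeFilling = suppressWarnings(rangeFilling(bin$binary,
                                                   presenceCells)),
      nMembersUsed = length(selected), memberTable = memberTable)
}

#' Metrics of an ensemble prediction as a one-row data.frame
#'
#' Columns mirror the per-species reporting convention: `n` (presence
#' cells is supplied by the caller), TSS, sensitivity, specificity,
#' binary cutoff, mean CV, range filling.
#'
#' @param x an [EnsemblePrediction-class].
#' @param n number of presences used to fit (stored alongside).
#' @param species,variant labels.
#' @return a one-row data.frame.
#' @export
ensembleMetrics <- function(x, n = NA_integer_, species = NA_character_,
                            variant = NA_character_) {
  data.frame(species = species, tier = x@tier, variant = variant, n = n,
             tss = x@tss, sensitivity = x@sensitivity,
             specificity = x@specificity, cutoff = x@cutoff,
             meanCv = x@meanCv, rangeFilling = x@rangeFilling,
             nMembersUsed = x@nMembersUsed, stringsAsFactors = FALSE)
}

setMethod("show", "EnsemblePrediction", function(object) {
  cat(sprintf(
    "EnsemblePrediction (%s): %d member(s), TSS %.3f (sens %.3f, spec %.3f), cutoff %.2f, mean CV %.3f, range filling %s\n",
    object@tier, object@nMembersUsed, object@tss, object@sensitivity,
    object@specificity, object@cutoff, object@meanCv,
    ifelse(is.na(object@rangeFilling), "NA",
           sprintf("%.3f", object@rangeFilling))))
})
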