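#' Variance inflation factor of one variable
#'
#' `1 / (1 - R^2)` where `R^2` comes from an ordinary least squares
#' regression of the target column on all other columns. An essentially
#' perfect fit (`R^2 >= 1 - 1e-12`) returns `Inf`.
#'
#' @param x data.frame or matrix of predictor values (>= 2 columns,
#'   >= ncol + 2 complete rows).
#' @param target name of the column to assess.
#' @return a single numeric (possibly `Inf`).
#' @export
vif <- function(x, target) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("vif needs at least 2 variables")
  if (!target %in% names(x)) stop("unknown target variable: ", target)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < ncol(x) + 2)
    stop("vif needs at least n_vars + 2 complete rows")
  y <- x[[target]]
  if (stats::sd(y) == 0)
    stop("degenerate variable: '", target, "' is constant")
  X <- cbind(1, as.matrix(x[setdiff(names(x), target)]))
  fit <- stats::lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' Stepwise VIF predictor selection
#'
#' Repeatedly removes the variable with the largest VIF while any VIF
#' exceeds the threshold (ties broken by earliest column order), then
#' reports the retained set, whose VIFs are all at most the threshold.
#'
#' @param x data.frame or matrix of predictor values.
#' @param threshold removal threshold (default 4).
#' @param tier label stored on the selection.
#' @return a [PredictorSelection-class].
#' @export
vifStep <- function(x, threshold = 4, tier = "unspecified") {
  x <- as.data.frame(x)
  if (!ncol(x)) stop("vifStep needs at least one variable")
  dropped <- data.frame(name = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  while (ncol(x) >= 2) {
    vifs <- vapply(names(x), function(nm) vif(x, nm), numeric(1))
    if (max(vifs) <= threshold) break
    worst <- which.max(vifs)           # first index on ties
    dropped <- rbind(dropped,
                     data.frame(name = names(x)[worst], vif = vifs[[worst]],
                                stringsAsFactors = FALSE))
    x <- x[, -worst, drop = FALSE]
  }
  new("PredictorSelection", tier = tier, retained = names(x),
      dropped = dropped, threshold = threshold)
}

setMethod("show", "PredictorSelection", function(object) {
  cat(sprintf("PredictorSelection (%s, VIF threshold %g):\n  retained: %s\n",
              object@tier, object@threshold,
              paste(object@retained, collapse = ", ")))
  if (nrow(object@dropped))
    cat("  dropped: ",
        paste(sprintf("%s (VIF %.3g)", object@dropped$name,
                      object@dropped$vif), collapse = ", "), "\n")
})

#' @describeIn vifStep retained variable names.
#' @param selection a [PredictorSelection-class].
#' @export
retainedPredictors <- function(selection) selection@retained

#' Assemble and collinearity-screen the predictor stack of a model tier
#'
#' The global tier keeps climate-prefixed layers only (climate is
#' assumed to be the sole constraint at the global scale); the regional
#' tier keeps all layers. Stepwise VIF selection then runs on the values
#' of all cells that are valid in every candidate layer.
#'
#' @param stack a [RasterStack-class] whose layer names carry
#'   `climate`/`habitat` prefixes.
#' @param tier `"global_climatic"` or `"regional_full"`.
#' @param vifThreshold removal threshold (default 4).
#' @return a list with elements `stack` (the retained
#'   [RasterStack-class]) and `selection` (the
#'   [PredictorSelection-class]).
#' @export
buildTierStack <- function(stack,
                           tier = c("global_climatic", "regional_full"),
                           vifThreshold = 4) {
  tier <- match.arg(tier)
  nm <- layerNames(stack)
  cand <- if (tier == "global_climatic") nm[grepl("^climate", nm)] else nm
  if (!length(cand))
    stop("no climate-prefixed layers available for the global tier")
  sub <- subsetStack(stack, cand)
  X <- stackValues(sub)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  sel <- if (ncol(X) >= 2) vifStep(X, vifThreshold, tier = tier)
         else new("PredictorSelection", tier = tier, retained = cand,
                  dropped = data.frame(name = character(), vif = numeric()),
                  threshold = vifThreshold)
  list(stack = subsetStack(sub, sel@retained), selection = sel)
}

#' Write a predictor-selection report
#' @param selection a [PredictorSelection-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeSelectionReport <- function(selection, path) {
  rows <- rbind(
    data.frame(tier = selection@tier, name = selection@retained,
               status = "retained", vifAtRemoval = NA_real_,
               stringsAsFactors = FALSE),
    if (nrow(selection@dropped))
      data.frame(tier = selection@tier, name = selection@dropped$name,
                 status = "dropped", vifAtRemoval = selection@dropped$vif,
                 stringsAsFactors = FALSE))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
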