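#' Default ensemble configuration
#'
#' Collects the tunable parameters of one ensemble fit. Defaults follow
#' the method's study design: five learners, three pseudo-absence sets,
#' four 70/30 cross-validation runs (60 members), member selection at
#' TSS >= 0.7 with a top-10%-quantile fallback, and a 0.01 cutoff
#' lattice. Boosting defaults are depth 3, 1000 trees, shrinkage 0.01.
#'
#' @param algorithms learner roster, a subset of `glm_logistic`,
#'   `gam_spline`, `fda`, `gbm`, `maxent_like`.
#' @param nPseudoAbsences pseudo-absence cells per set.
#' @param nPaSets,nCvRuns numbers of pseudo-absence sets and
#'   cross-validation repetitions.
#' @param trainFraction training share of each split.
#' @param tssMin member-selection threshold.
#' @param fallbackQuantile top quantile used when no member reaches
#'   `tssMin`.
#' @param cutoffStep lattice step for threshold optimization.
#' @param gamK basis dimension of each GAM smoother.
#' @param gbmTrees,gbmDepth,gbmShrinkage boosting hyperparameters.
#' @param maxentLambda lasso penalty of the regularized-logistic
#'   (maxent-like) learner.
#' @return a list of class `ensembleConfig`.
#' @export
ensembleConfig <- function(algorithms = c("glm_logistic", "gam_spline",
                                          "fda", "gbm", "maxent_like"),
                           nPseudoAbsences = 5000L, nPaSets = 3L,
                           nCvRuns = 4L, trainFraction = 0.7,
                           tssMin = 0.7, fallbackQuantile = 0.1,
                           cutoffStep = 0.01, gamK = 5L,
                           gbmTrees = 1000L, gbmDepth = 3L,
                           gbmShrinkage = 0.01, maxentLambda = 0.01) {
  known <- c("glm_logistic", "gam_spline", "fda", "gbm", "maxent_like")
  bad <- setdiff(algorithms, known)
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "))
  structure(list(algorithms = algorithms,
                 nPseudoAbsences = as.integer(nPseudoAbsences),
                 nPaSets = as.integer(nPaSets),
                 nCvRuns = as.integer(nCvRuns),
                 trainFraction = trainFraction, tssMin = tssMin,
                 fallbackQuantile = fallbackQuantile,
                 cutoffStep = cutoffStep, gamK = as.integer(gamK),
                 gbmTrees = as.integer(gbmTrees),
                 gbmDepth = as.integer(gbmDepth),
                 gbmShrinkage = gbmShrinkage,
                 maxentLambda = maxentLambda),
            class = "ensembleConfig")
}

scaleByTraining <- function(X, center, scale) {
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)

fitLearner <- function(algorithm, Xs, y, w, params) {
  vars <- colnames(Xs)
  df <- as.data.frame(Xs)
  df$y <- y
  df$w <- w
  switch(algorithm,
    glm_logistic = {
      f <- stats::as.formula(paste("y ~",
        paste(c(vars, sprintf("I(%s^2)", vars)), collapse = " + ")))
      list(model = stats::glm(f, family = stats::quasibinomial(),
                              data = df, weights = w))
    },
    gam_spline = {
      k <- params$gamK
      f <- stats::as.formula(paste("y ~",
        paste(sprintf("s(%s, k = %d)", vars, k), collapse = " + ")))
      list(model = mgcv::gam(f, family = stats::quasibinomial(),
                             data = df, weights = w))
    },
    fda = {
      # optimal scoring for 2 classes = weighted least squares of the
      # class indicator on a spline basis, then logistic calibration
      f <- stats::as.formula(paste("y ~",
        paste(sprintf("splines::ns(%s, df = 3)", vars), collapse = " + ")))
      score <- stats::lm(f, data = df, weights = w)
      df$sc <- stats::fitted(score)
      calib <- stats::glm(y ~ sc, family = stats::quasibinomial(),
                          data = df, weights = w)
      list(model = score, calib = calib)
    },
    gbm = {
      dtr <- xgboost::xgb.DMatrix(Xs, label = y, weight = w)
      list(model = xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$gbmDepth,
                      eta = params$gbmShrinkage, nthread = 1),
        data = dtr, nrounds = params$gbmTrees, verbose = 0))
    },
    maxent_like = {
      Xf <- cbind(Xs, `colnames<-`(Xs^2, paste0(vars, "_sq")))
      lam <- params$maxentLambda
      list(model = glmnet::glmnet(Xf, y, family = "binomial",
                                  weights = w, alpha = 1,
                                  lambda = c(lam * 10, lam)),
           lambda = lam)
    },
    stop("unknown algorithm: ", algorithm))
}

predictLearner <- function(algorithm, fit, Xs) {
  df <- as.data.frame(Xs)
  p <- switch(algorithm,
    glm_logistic = stats::predict(fit$model, newdata = df,
                                  type = "response"),
    gam_spline = as.numeric(stats::predict(fit$model, newdata = df,
                                           type = "response")),
    fda = {
      sc <- stats::predict(fit$model, newdata = df)
      co <- stats::coef(fit$calib)
      if (anyNA(co)) rep(mean(stats::fitted(fit$calib)), nrow(df))
      else stats::plogis(co[1] + co[2] * sc)
    },
    gbm = stats::predict(fit$model, xgboost::xgb.DMatrix(Xs)),
    maxent_like = {
      vars <- colnames(Xs)
      Xf <- cbind(Xs, `colnames<-`(Xs^2, paste0(vars, "_sq")))
      as.numeric(stats::predict(fit$model, Xf, s = fit$lambda,
                                type = "response"))
    },
    stop("unknown algorithm: ", algorithm))
  clamp01(as.numeric(p))
}

#' Fit one ensemble member
#'
#' Fits a probabilistic presence/pseudo-absence classifier on the
#' training split (presences carry weight 1, pseudo-absence reliability
#' weights enter the fitting criterion as multiplicative case weights),
#' then evaluates it on the held-out split: the member cutoff is the
#' TSS-maximizing lattice value and the stored metrics are taken there.
#'
#' @param algorithm one of `glm_logistic`, `gam_spline`, `fda`, `gbm`,
#'   `maxent_like`.
#' @param X numeric matrix of predictor values, one row per grid cell
#'   (row index = cell index), named columns.
#' @param train,eval lists with elements `presences` (cell indices),
#'   `paCells`, `paWeights`.
#' @param params an [ensembleConfig()] list.
#' @param paSetId,cvRunId integer provenance labels.
#' @return a [FittedMember-class].
#' @export
fitMember <- function(algorithm, X, train, eval,
                      params = ensembleConfig(), paSetId = 1L,
                      cvRunId = 1L) {
  if (!length(train$presences) || !length(train$paCells))
    stop("degenerate training data: both classes are required")
  if (!length(eval$presences) || !length(eval$paCells))
    stop("degenerate evaluation data: both classes are required")
  trCells <- c(train$presences, train$paCells)
  y <- c(rep(1, length(train$presences)), rep(0, length(train$paCells)))
  w <- c(rep(1, length(train$presences)), train$paWeights)
  Xtr <- X[trCells, , drop = FALSE]
  if (anyNA(Xtr)) stop("predictor values missing at training cells")
  # weighted standardization so zero-weight cases leave no trace
  center <- apply(Xtr, 2, stats::weighted.mean, w = w)
  scale <- sqrt(colSums(w * sweep(Xtr, 2, center)^2) / sum(w))
  scale[!is.finite(scale) | scale == 0] <- 1
  fit <- fitLearner(algorithm, scaleByTraining(Xtr, center, scale), y, w,
                    params)
  fit$center <- center
  fit$scale <- scale
  fit$algorithm <- algorithm
  evCells <- c(eval$presences, eval$paCells)
  yEv <- c(rep(1, length(eval$presences)), rep(0, length(eval$paCells)))
  pEv <- predictLearner(algorithm, fit,
                        scaleByTraining(X[evCells, , drop = FALSE],
                                        center, scale))
  lattice <- seq(0, 1, by = params$cutoffStep)
  ev <- evaluateBinary(pEv, yEv, lattice)
  new("FittedMember", algorithm = algorithm, paSetId = as.integer(paSetId),
      cvRunId = as.integer(cvRunId), fit = fit,
      evalSensitivity = ev$sensitivity, evalSpecificity = ev$specificity,
      evalTss = ev$tss, memberCutoff = ev$cutoff)
}

#' Predict a fitted member over predictor rows
#'
#' @param member a [FittedMember-class].
#' @param X numeric matrix of predictor values (complete rows).
#' @return numeric vector of suitabilities in [0, 1].
#' @export
predictMember <- function(member, X) {
  predictLearner(member@algorithm, member@fit,
                 scaleByTraining(X, member@fit$center, member@fit$scale))
}

setMethod("show", "FittedMember", function(object) {
  cat(sprintf(
    "FittedMember %s (PA set %d, run %d): eval TSS %.3f (sens %.3f, spec %.3f) at cutoff %.2f\n",
    object@algorithm, object@paSetId, object@cvRunId, object@evalTss,
    object@evalSensitivity, object@evalSpecificity, object@memberCutoff))
})
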