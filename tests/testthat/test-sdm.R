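test_that("pseudo-absence sampling excludes presences and is reproducible", {
  g <- gridSpec(0, 0, 0.25, 10, 10)
  mask <- rasterLayer(g, 1, "mask")
  pres <- 1:20
  pa <- samplePseudoAbsences(mask, 50, pres, seed = 3)
  expect_length(pa@cells, 50)
  expect_length(intersect(pa@cells, pres), 0)
  expect_true(all(pa@weights == 1))
  pa2 <- samplePseudoAbsences(mask, 50, pres, seed = 3)
  expect_identical(pa2@cells, pa@cells)
  # n equal to the candidate count selects every candidate
  all80 <- samplePseudoAbsences(mask, 80, pres, seed = 1)
  expect_setequal(all80@cells, setdiff(1:100, pres))
  expect_error(samplePseudoAbsences(mask, 81, pres, seed = 1),
               "81 requested, 80 available")
})

test_that("the inverse-logistic pseudo-absence weight follows its contract", {
  g <- gridSpec(0, 0, 0.25, 1, 5)
  pa <- new("PseudoAbsenceSet", id = 1L, cells = 1:5,
            weights = rep(1, 5))
  projG <- rasterLayer(g, c(1, 0, 0.5, 0.8, 0.2), "projG")
  w <- weightPseudoAbsences(pa, projG)@weights
  expect_equal(w[1], 0)            # fully suitable -> no absence signal
  expect_equal(w[2], 1)            # unsuitable -> full absence
  expect_equal(w[3], 0.5)
  expect_equal(w[4], 1 / 17)
  expect_equal(w[4] + w[5], 1)     # complement symmetry
  bad <- rasterLayer(g, c(1.2, 0, 0, 0, 0), "projG")
  expect_error(weightPseudoAbsences(pa, bad), "\\[0, 1\\]")
})

test_that("train/eval splits are stratified, disjoint and exhaustive", {
  pres <- 101:200
  pa <- new("PseudoAbsenceSet", id = 1L, cells = 1:80,
            weights = seq(0, 1, length.out = 80))
  sp <- splitTrainEval(pres, pa, 0.7, seed = 5)
  expect_length(sp$train$presences, 70)
  expect_length(sp$eval$presences, 30)
  expect_length(intersect(sp$train$presences, sp$eval$presences), 0)
  expect_setequal(c(sp$train$presences, sp$eval$presences), pres)
  expect_setequal(c(sp$train$paCells, sp$eval$paCells), pa@cells)
  # weights travel with their cells
  expect_equal(sp$train$paWeights, pa@weights[match(sp$train$paCells,
                                                    pa@cells)])
  others <- vapply(6:9, function(s)
    identical(splitTrainEval(pres, pa, 0.7, seed = s)$train$presences,
              sp$train$presences), logical(1))
  expect_false(any(others))
  expect_error(splitTrainEval(1:9, pa, 0.7, 1), "too few presences")
})

test_that("threshold-optimized metrics match hand-built confusion tables", {
  # counts chosen to give sensitivity 0.9509 and specificity 0.8763
  scores <- c(rep(0.9, 9509), rep(0.1, 491), rep(0.1, 8763),
              rep(0.9, 1237))
  labels <- c(rep(1, 10000), rep(0, 10000))
  ev <- evaluateBinary(scores, labels)
  expect_equal(ev$sensitivity, 0.9509)
  expect_equal(ev$specificity, 0.8763)
  expect_equal(ev$tss, 0.8272, tolerance = 1e-12)
  # perfect separation: TSS 1, smallest tied cutoff reported
  pv <- evaluateBinary(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(pv$tss, 1)
  expect_equal(pv$cutoff, 0.01)
  set.seed(61)
  rnd <- evaluateBinary(runif(10000), rbinom(10000, 1, 0.4))
  expect_lt(abs(rnd$tss), 0.05)
  expect_error(evaluateBinary(runif(5), rep(1, 5)), "both classes")
})

test_that("TSS is permutation invariant and antisymmetric under complement", {
  set.seed(67)
  scores <- runif(500)
  labels <- rbinom(500, 1, 0.3)
  ev <- evaluateBinary(scores, labels)
  idx <- sample(500)
  expect_equal(evaluateBinary(scores[idx], labels[idx]), ev)
  # brute-force oracle at the reported cutoff
  pred <- scores >= ev$cutoff
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  expect_equal(ev$sensitivity, tp / (tp + fn))
  expect_equal(ev$specificity, tn / (tn + fp))
  expect_equal(ev$tss, ev$sensitivity + ev$specificity - 1)
  # at a fixed cutoff the complement classifier has TSS of opposite sign
  at5 <- evaluateBinary(scores, labels, cutoffLattice = 0.5)
  comp5 <- evaluateBinary(1 - scores, labels, cutoffLattice = 0.5)
  expect_equal(comp5$tss, -at5$tss, tolerance = 1e-12)
})

test_that("member selection keeps skilled members and never returns empty", {
  mk <- function(tss) new("FittedMember", algorithm = "glm_logistic",
                          paSetId = 1L, cvRunId = 1L, fit = list(),
                          evalSensitivity = (tss + 1) / 2,
                          evalSpecificity = (tss + 1) / 2,
                          evalTss = tss, memberCutoff = 0.5)
  sel <- selectMembers(list(mk(0.8), mk(0.72), mk(0.5)))
  expect_equal(vapply(sel, function(m) m@evalTss, numeric(1)),
               c(0.8, 0.72))
  low <- lapply(seq(0.1, 0.69, length.out = 60), mk)
  expect_length(selectMembers(low), 6)   # ceil(10% of 60)
  expect_length(selectMembers(list(mk(0.1))), 1)
})

test_that("committee averaging matches hand computation on binary votes", {
  B <- cbind(c(1, 1, 0, 1), c(0, 1, 0, 1))   # 4 cells x 2 members
  comm <- hierSDM:::committeeFromBinaries(B)
  expect_equal(comm$mean, c(0.5, 1, 0, 1))
  # cell 1: sd_pop 0.5, mean 0.5 -> raw cv 1 = map max -> 1; mean 0 -> 0
  expect_equal(comm$cv, c(1, 0, 0, 0))
  # committee means live on the k/N lattice
  set.seed(71)
  B2 <- matrix(rbinom(60, 1, 0.5), 12, 5)
  m5 <- hierSDM:::committeeFromBinaries(B2)$mean * 5
  expect_true(all(abs(m5 - round(m5)) < 1e-9))
})

test_that("ensemble binarization and range filling follow their definitions", {
  g <- gridSpec(0, 0, 0.25, 5, 5)
  s <- rasterLayer(g, c(rep(1, 5), rep(0, 20)), "s")
  b <- binarizeEnsemble(s, presenceCells = 1:5, paCells = 6:25)
  expect_equal(b$tss, 1)
  expect_equal(b$cutoff, 0.01)
  flat <- binarizeEnsemble(rasterLayer(g, 0.5, "s"), 1:5, 6:25)
  expect_equal(flat$tss, 0)
  bin <- rasterLayer(g, c(rep(1, 10), rep(0, 15)), "b")
  expect_equal(rangeFilling(bin, presenceCells = c(1:4, 20)), 0.4)
  expect_equal(rangeFilling(bin, 1:10), 1)
  expect_equal(rangeFilling(bin, 11:15), 0)
  expect_warning(rf <- rangeFilling(rasterLayer(g, 0, "b"), 1:3),
                 "undefined")
  expect_true(is.na(rf))
})

test_that("learners separate separable data and stay null on noise", {
  g <- gridSpec(0, 0, 0.25, 40, 40)
  set.seed(81)
  X <- cbind(x1 = rnorm(1600), x2 = rnorm(1600))
  sep <- which(X[, "x1"] > 1)
  notSep <- which(X[, "x1"] < -1)
  train <- list(presences = sep[1:100], paCells = notSep[1:100],
                paWeights = rep(1, 100))
  eval <- list(presences = sep[101:160], paCells = notSep[101:160],
               paWeights = rep(1, 60))
  m <- suppressWarnings(fitMember("glm_logistic", X, train, eval))
  expect_equal(m@evalTss, 1)
  # labels independent of predictors stay near TSS 0
  set.seed(83)
  cells <- sample(1600, 1000)
  trainN <- list(presences = cells[1:350], paCells = cells[351:700],
                 paWeights = rep(1, 350))
  evalN <- list(presences = cells[701:850], paCells = cells[851:1000],
                paWeights = rep(1, 150))
  for (alg in c("glm_logistic", "fda")) {
    mn <- suppressWarnings(fitMember(alg, X, trainN, evalN))
    expect_lt(abs(mn@evalTss), 0.15)
  }
  expect_error(fitMember("glm_logistic", X,
                         list(presences = sep[1:20], paCells = integer(),
                              paWeights = numeric()), eval),
               "both classes")
})

test_that("pseudo-absence case weights act through the fitting criterion", {
  g <- gridSpec(0, 0, 0.25, 30, 30)
  set.seed(91)
  X <- cbind(x1 = rnorm(900), x2 = rnorm(900))
  p <- plogis(1.5 * X[, "x1"])
  pres <- sample(900, 200, prob = p)
  pa <- setdiff(sample(900, 500), pres)[1:250]
  w <- runif(250)
  w[1:60] <- 0
  tr <- list(presences = pres[1:140], paCells = pa[1:175],
             paWeights = w[1:175])
  ev <- list(presences = pres[141:200], paCells = pa[176:250],
             paWeights = w[176:250])
  mW <- fitMember("glm_logistic", X, tr, ev)
  # zero-weight pseudo-absences have no influence: drop them outright
  keep <- tr$paWeights > 0
  trD <- list(presences = tr$presences, paCells = tr$paCells[keep],
              paWeights = tr$paWeights[keep])
  mD <- fitMember("glm_logistic", X, trD, ev)
  expect_equal(coef(mW@fit$model), coef(mD@fit$model), tolerance = 1e-6)
  # doubling all pseudo-absence weights only shifts the intercept,
  # which the cutoff search absorbs
  tr2 <- tr; tr2$paWeights <- pmin(tr$paWeights * 2, 1)
  m2 <- fitMember("glm_logistic", X, tr, ev)
  expect_equal(m2@evalTss, mW@evalTss, tolerance = 0.02)
})
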