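mkStack <- function(values, nm = "climate1") {
  g <- gridSpec(0, 0, 0.25, 1, length(values))
  rasterStack(stats::setNames(list(rasterLayer(g, values, nm)), nm))
}

test_that("MESS hits its branch values and flags extrapolation", {
  ref <- matrix(1:10, ncol = 1, dimnames = list(NULL, "climate1"))
  # target at the reference median: p = 50 -> similarity 100
  st <- mkStack(c(5.5, 0, 1, 11, 10, 3))
  ms <- layerValues(messLayer(ref, st))
  expect_equal(ms[1], 100)
  expect_lt(ms[2], 0)              # below the minimum: extrapolation
  expect_equal(ms[3], 0)           # at the minimum: p = 0 branch gives 0
  expect_lt(ms[4], 0)              # above the maximum
  expect_equal(ms[5], 20)          # p = 90% -> 2(100 - p)
  expect_equal(ms[6], 2 * 20)      # p = 20% -> 2p
  # reference points against their own reference set never extrapolate
  own <- mkStack(as.numeric(1:10))
  expect_true(all(layerValues(messLayer(ref, own)) >= 0))
  expect_warning(
    expect_error(messLayer(matrix(rep(1, 5), ncol = 1,
                                  dimnames = list(NULL, "climate1")), st),
                 "degenerate"),
    "constant")
})

test_that("vectorized MESS equals the per-point per-variable loop oracle", {
  set.seed(101)
  nRef <- 60
  ref <- cbind(a = rnorm(nRef), b = runif(nRef), c = rnorm(nRef, sd = 3))
  g <- gridSpec(0, 0, 0.25, 20, 20)
  tgt <- rasterStack(list(a = rasterLayer(g, rnorm(400, sd = 1.5), "a"),
                          b = rasterLayer(g, runif(400, -0.5, 1.5), "b"),
                          c = rasterLayer(g, rnorm(400, sd = 4), "c")))
  ms <- layerValues(messLayer(ref, tgt))
  oracle <- vapply(seq_len(400), function(i) {
    sims <- vapply(colnames(ref), function(v) {
      t <- layerValues(tgt@layers[[v]])[i]
      r <- ref[, v]
      p <- 100 * sum(r < t) / length(r)
      if (p == 0) (t - min(r)) / (max(r) - min(r)) * 100
      else if (p == 100) (max(r) - t) / (max(r) - min(r)) * 100
      else if (p <= 50) 2 * p
      else 2 * (100 - p)
    }, numeric(1))
    min(sims)
  }, numeric(1))
  expect_equal(ms, oracle, tolerance = 1e-12)
  # affine equivariance: rescaling a variable in both sets changes nothing
  ref2 <- ref; ref2[, "a"] <- 10 + 3 * ref[, "a"]
  tgt2 <- tgt
  tgt2@layers[["a"]] <- rasterLayer(g, 10 + 3 * layerValues(tgt@layers[["a"]]), "a")
  expect_equal(layerValues(messLayer(ref2, tgt2)), ms, tolerance = 1e-9)
})

test_that("the dissimilar-species proportion counts negative MESS per cell", {
  g <- gridSpec(0, 0, 0.25, 2, 2)
  mk <- function(v) rasterLayer(g, v, "mess")
  layers <- list(mk(c(-1, 5, 5, NA)), mk(c(-2, -1, 5, NA)),
                 mk(c(3, 5, 5, 4)))
  pr <- layerValues(messProportion(layers))
  expect_equal(pr[1], 2 / 3)
  expect_equal(pr[2], 1 / 3)
  expect_equal(pr[3], 0)
  expect_equal(pr[4], 0)           # only the valid species counts
})

test_that("ignorance follows the half-saturation form and tracks effort bias", {
  g <- gridSpec(0, 0, 0.25, 8, 8)
  recs <- makeRecords(lon = c(0.1, 0.1, 0.3, 0.3, 0.3),
                      lat = c(0.1, 0.1, 0.1, 0.1, 0.1))
  ign <- ignoranceMap(recs, g, halfSaturation = 2)
  v <- ign@values
  expect_equal(v[1], 2 / 4)        # n = 2 = h -> 0.5... at h = 2: 2/(2+2)
  expect_equal(v[2], 2 / 5)        # n = 3
  expect_equal(v[3], 1)            # empty cell
  expect_true(all(diff(ign@rescaled[order(v)]) >= 0))
  expect_true(v[3] > v[1] && v[1] > v[2])  # decreasing in record count
  # biased sampling leaves ignorance anticorrelated with effort
  gg <- gridSpec(0, 0, 0.25, 25, 25)
  set.seed(103)
  effort <- plogis(2 * layerValues(generateEnvironment(
    gg, 1, 1, 4, seed = 11)@layers[["climate1"]]))
  cfg <- virtualSpeciesConfig("v", c(climate1 = 1e-12), nRecords = 1500,
                              pErrorRecords = 0,
                              pMissingUncertainty = 0, seed = 5)
  recsB <- sampleOccurrences(rasterLayer(gg, 0.5, "t"), cfg,
                             bias = rasterLayer(gg, effort, "bias"))
  ignB <- ignoranceMap(recsB, gg)
  expect_lt(cor(ignB@values, effort, method = "spearman"), -0.3)
})

test_that("Bhattacharyya distance behaves as a divergence on normalized maps", {
  g <- gridSpec(0, 0, 0.25, 1, 2)
  a <- rasterLayer(g, c(0.5, 0.5), "a")
  b <- rasterLayer(g, c(0.9, 0.1), "b")
  expect_equal(bhattacharyyaDistance(a, a), 0)
  d <- bhattacharyyaDistance(a, b)
  expect_equal(d, -log(sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)
  expect_equal(bhattacharyyaDistance(b, a), d)   # symmetry
  disj <- bhattacharyyaDistance(rasterLayer(g, c(1, 0), "x"),
                                rasterLayer(g, c(0, 1), "y"))
  expect_identical(disj, Inf)
  expect_error(bhattacharyyaDistance(a, rasterLayer(g, c(0, 0), "z")),
               "all-zero")
  expect_error(bhattacharyyaDistance(a, rasterLayer(g, c(-1, 2), "w")),
               "nonnegative")
})
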