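test_that("generated environments are standardized, tagged and reproducible", {
  g <- gridSpec(0, 0, 0.25, 30, 30)
  st <- generateEnvironment(g, 3, 2, 3, duplicatePairs = 1, seed = 7)
  expect_setequal(layerNames(st),
                  c("climate1", "climate2", "climate3", "habitat1",
                    "habitat2", "climate1_dup"))
  X <- stackValues(st)
  expect_equal(colMeans(X), rep(0, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(X, 2, sd), rep(1, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gt(abs(cor(X[, "climate1"], X[, "climate1_dup"])), 0.99)
  st2 <- generateEnvironment(g, 3, 2, 3, duplicatePairs = 1, seed = 7)
  expect_identical(stackValues(st2), X)      # bitwise determinism
  expect_error(generateEnvironment(gridSpec(0, 0, 0.25, 5, 5), 1, 1,
                                   autocorrRangeCells = 4, seed = 1),
               "too small")
})

test_that("zero smoothing range yields spatially white layers", {
  g <- gridSpec(0, 0, 0.25, 50, 50)
  st <- generateEnvironment(g, 1, 1, autocorrRangeCells = 0, seed = 13)
  # lag-1 Moran-type autocorrelation along rows, against a white-noise
  # oracle expectation of 0
  M <- matrix(layerValues(st@layers[["climate1"]]), 50, 50, byrow = TRUE)
  lag1 <- cor(as.numeric(M[, -1]), as.numeric(M[, -50]))
  expect_lt(abs(lag1), 0.1)
  stS <- generateEnvironment(g, 1, 1, autocorrRangeCells = 4, seed = 13)
  MS <- matrix(layerValues(stS@layers[["climate1"]]), 50, 50, byrow = TRUE)
  expect_gt(cor(as.numeric(MS[, -1]), as.numeric(MS[, -50])), 0.5)
})

test_that("true suitability follows the logistic model and hits prevalence targets", {
  g <- gridSpec(0, 0, 0.25, 5, 5)
  x <- seq(-2, 2, length.out = 25)
  st <- rasterStack(list(climate1 = rasterLayer(g, x, "climate1")))
  cfgFlat <- virtualSpeciesConfig("v", c(climate1 = 1e-12), intercept = 0,
                                  seed = 1)
  expect_equal(layerValues(trueSuitability(st, cfgFlat)), rep(0.5, 25),
               tolerance = 1e-9)
  cfgLow <- virtualSpeciesConfig("v", c(climate1 = 1e-12),
                                 intercept = -50, seed = 1)
  expect_true(all(layerValues(trueSuitability(st, cfgLow)) < 1e-20))
  cfgB <- virtualSpeciesConfig("v", c(climate1 = 1), intercept = 0,
                               seed = 1)
  s <- trueSuitability(st, cfgB)
  expect_equal(layerValues(s)[x == 0], 0.5)      # x = 0 sits at 0.5
  expect_equal(layerValues(s), plogis(x))
  cfgPrev <- virtualSpeciesConfig("v", c(climate1 = 2),
                                  prevalenceTarget = 0.2, seed = 1)
  expect_equal(mean(layerValues(trueSuitability(st, cfgPrev))), 0.2,
               tolerance = 0.005)
  expect_error(trueSuitability(st, virtualSpeciesConfig(
    "v", c(nosuch = 1), seed = 1)), "unknown predictor")
})

test_that("occurrence sampling respects suitability, bias and error settings", {
  g <- gridSpec(0, 0, 0.25, 10, 10)
  uniform <- rasterLayer(g, 0.5, "truth")
  cfgClean <- virtualSpeciesConfig("v", c(climate1 = 1), nRecords = 300,
                                   pErrorRecords = 0,
                                   pMissingUncertainty = 0, seed = 2)
  recs <- sampleOccurrences(uniform, cfgClean)
  expect_identical(unique(recs$rawFlag), "")
  expect_false(anyNA(recs$coordinateUncertaintyInMeters))
  expect_true(all(recs$basisOfRecord %in%
                  c("human_observation", "machine_observation")))
  # bias restricted to the west half confines all records there
  west <- rasterLayer(g, rep(rep(c(1, 0), each = 5), 10), "bias")
  recsW <- sampleOccurrences(uniform, cfgClean, bias = west)
  expect_true(all(recsW$decimalLongitude < 0 + 5 * 0.25))
  # an indicator truth confines every uncorrupted record to truth = 1
  ind <- rasterLayer(g, as.numeric(seq_len(100) %in% 40:60), "truth")
  cfgErr <- virtualSpeciesConfig("v", c(climate1 = 1), nRecords = 200,
                                 pErrorRecords = 0.1, seed = 3)
  recsI <- sampleOccurrences(ind, cfgErr)
  clean <- recsI[recsI$rawFlag == "", ]
  cells <- pointToCell(g, clean$decimalLongitude, clean$decimalLatitude)
  expect_true(all(layerValues(ind)[cells] == 1))
  expect_error(sampleOccurrences(rasterLayer(g, 0, "t"), cfgClean),
               "no suitable habitat")
  # determinism under the stored seed
  expect_identical(sampleOccurrences(uniform, cfgClean), recs)
})

test_that("uniform sampling produces multinomially uniform cell counts", {
  g <- gridSpec(0, 0, 0.25, 10, 10)
  uniform <- rasterLayer(g, 1, "truth")
  cfg <- virtualSpeciesConfig("v", c(climate1 = 1), nRecords = 2000,
                              pErrorRecords = 0, pMissingUncertainty = 0,
                              seed = 9)
  recs <- sampleOccurrences(uniform, cfg)
  cells <- pointToCell(g, recs$decimalLongitude, recs$decimalLatitude)
  counts <- tabulate(cells, nbins = 100)
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("occurrence tables round-trip through the Darwin-Core-like CSV", {
  g <- gridSpec(0, 0, 0.25, 6, 6)
  cfg <- virtualSpeciesConfig("v sp", c(climate1 = 1), nRecords = 50,
                              seed = 4)
  recs <- sampleOccurrences(rasterLayer(g, 0.7, "t"), cfg)
  path <- file.path(tempdir(), "occ.csv")
  writeOccurrences(recs, path)
  back <- readOccurrences(path)
  expect_equal(back$decimalLongitude, recs$decimalLongitude)
  expect_identical(back$species, recs$species)
  expect_equal(back$coordinateUncertaintyInMeters,
               recs$coordinateUncertaintyInMeters)
  expect_error(readOccurrences({
    p <- file.path(tempdir(), "bad.csv")
    write.csv(data.frame(a = 1), p, row.names = FALSE); p
  }), "lacks column")
})
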