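test_that("richness stacking sums binaries with a loop oracle", {
  g <- gridSpec(0, 0, 0.25, 4, 4)
  ones <- replicate(15, rasterLayer(g, 1, "b"), simplify = FALSE)
  expect_true(all(layerValues(stackRichness(ones)) == 15))
  zeros <- replicate(3, rasterLayer(g, 0, "b"), simplify = FALSE)
  expect_true(all(layerValues(stackRichness(zeros)) == 0))
  set.seed(111)
  rnd <- replicate(6, rasterLayer(g, {
    v <- rbinom(16, 1, 0.5); v[sample(16, 2)] <- NA; v
  }, "b"), simplify = FALSE)
  r <- layerValues(stackRichness(rnd))
  oracle <- sapply(seq_len(16), function(i) {
    v <- vapply(rnd, function(l) layerValues(l)[i], numeric(1))
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  })
  expect_equal(r, oracle)
  g2 <- gridSpec(0, 0, 0.25, 2, 2)
  expect_error(stackRichness(list(ones[[1]], rasterLayer(g2, 1, "b"))),
               "share one grid")
  expect_error(stackRichness(list(rasterLayer(g, 0.5, "b"))), "0/1")
})

test_that("the mean CV map averages over species with valid values", {
  g <- gridSpec(0, 0, 0.25, 3, 3)
  a <- rasterLayer(g, 0.2, "cv")
  b <- rasterLayer(g, 0.8, "cv")
  expect_true(all(layerValues(meanCvMap(list(a, b))) == 0.5))
  expect_equal(layerValues(meanCvMap(list(a, a))), layerValues(a))
  withNA <- rasterLayer(g, c(NA, rep(0.4, 8)), "cv")
  m <- layerValues(meanCvMap(list(a, withNA)))
  expect_equal(m[1], 0.2)
  expect_equal(m[2], 0.3)
})

test_that("the classification tree reproduces the six-zone mapping", {
  g <- gridSpec(0, 0, 0.25, 1, 3)
  zl <- function(cv, rr, gr)
    zoneLegend()$letter[classifyZones(
      rasterLayer(g, cv, "cv"), rasterLayer(g, rr, "r"),
      rasterLayer(g, gr, "g"), cvThreshold = 0.5,
      richnessThreshold = 7, nSpecies = 15L)@zones[1]]
  expect_identical(zl(0.3, 10, 3), "B")   # certain + high richness
  expect_identical(zl(0.6, 3, 10), "D")   # uncertain climatic hotspot
  expect_identical(zl(0.5, 7, 7), "A")    # central values fall in 'low'
  expect_identical(zl(0.2, 5, 12), "A")
  expect_identical(zl(0.9, 9, 9), "F")
  expect_identical(zl(0.9, 9, 2), "E")
  expect_identical(zl(0.9, 2, 2), "C")
})

test_that("zones partition valid cells and respond monotonely to richness", {
  g <- gridSpec(0, 0, 0.25, 10, 10)
  set.seed(113)
  cv <- rasterLayer(g, runif(100), "cv")
  rr <- rasterLayer(g, sample(0:15, 100, TRUE), "r")
  gr <- rasterLayer(g, sample(0:15, 100, TRUE), "g")
  zm <- classifyZones(cv, rr, gr, nSpecies = 15L)
  expect_false(anyNA(zm@zones))
  st <- zoneStatistics(zm)
  expect_equal(sum(st$fraction), 1, tolerance = 1e-9)
  # raising regional richness at a certain cell can only move A -> B
  rr2 <- rasterLayer(g, pmin(layerValues(rr) + 5, 15), "r")
  zm2 <- classifyZones(cv, rr2, gr, richnessThreshold = 7,
                       nSpecies = 15L)
  certain <- layerValues(cv) <= 0.5
  expect_true(all(zm2@zones[certain] >= zm@zones[certain]))
  expect_false(any(zm@zones[certain] == 2L & zm2@zones[certain] == 1L))
  # threshold extremes collapse the tree onto its two halves
  allCertain <- classifyZones(cv, rr, gr, cvThreshold = 1,
                              richnessThreshold = 7, nSpecies = 15L)
  expect_true(all(allCertain@zones %in% 1:2))
  allUncertain <- classifyZones(cv, rr, gr, cvThreshold = 0,
                                richnessThreshold = 7, nSpecies = 15L)
  expect_true(all(allUncertain@zones %in% 3:6))
})

test_that("zone statistics summarize layers per zone and mark absent zones", {
  g <- gridSpec(0, 0, 0.25, 2, 3)
  zm <- classifyZones(rasterLayer(g, 0.1, "cv"),
                      rasterLayer(g, c(9, 9, 9, 2, 2, 2), "r"),
                      rasterLayer(g, 5, "g"),
                      richnessThreshold = 7, nSpecies = 15L)
  extra <- list(mess = rasterLayer(g, c(0.2, 0.4, 0.6, 0.1, 0.1, 0.4),
                                   "mess"))
  st <- zoneStatistics(zm, extra)
  expect_equal(st$fraction[st$zone == "B"], 0.5)
  expect_equal(st$messMean[st$zone == "B"], mean(c(0.2, 0.4, 0.6)))
  expect_equal(st$messMin[st$zone == "A"], 0.1)
  expect_equal(st$messMax[st$zone == "A"], 0.4)
  absent <- st[st$zone == "E", ]
  expect_identical(absent$nCells, 0L)
  expect_true(is.na(absent$messMean))
  single <- zoneStatistics(classifyZones(rasterLayer(g, 0.1, "cv"),
                                         rasterLayer(g, 9, "r"),
                                         rasterLayer(g, 9, "g"),
                                         richnessThreshold = 7,
                                         nSpecies = 15L))
  expect_equal(single$fraction[single$zone == "B"], 1)
})
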