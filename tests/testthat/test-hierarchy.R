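# small two-tier setup shared by the blocks below
miniSetup <- function(seed = 5) {
  wg <- gridSpec(-1, -1, 0.25, 26, 26)
  rg <- gridSpec(0, 0, 0.25, 18, 18)
  st <- generateEnvironment(wg, 2, 1, 3, seed = childSeed(seed, "env"))
  cfg <- virtualSpeciesConfig("mini_vsp",
                              c(climate1 = 2, climate2 = -2,
                                habitat1 = 2),
                              prevalenceTarget = 0.25, nRecords = 400L,
                              pErrorRecords = 0.03,
                              pMissingUncertainty = 0.3, seed = seed)
  recs <- sampleOccurrences(trueSuitability(st, cfg), cfg)
  config <- runConfig(globalEnsemble = quickEnsemble(nPseudoAbsences = 250L),
                      regionalEnsemble = quickEnsemble(nPseudoAbsences = 150L),
                      minPresences = 20L, masterSeed = seed)
  list(records = recs,
       worldTier = buildTierStack(st, "global_climatic"),
       regionTier = buildTierStack(cropToGrid(st, rg), "regional_full"),
       config = config, regionGrid = rg)
}

test_that("a species run is reproducible and keeps tiers on their own grids", {
  s <- miniSetup()
  r1 <- suppressWarnings(runSpecies(s$records, s$worldTier, s$regionTier,
                                    s$config))
  r2 <- suppressWarnings(runSpecies(s$records, s$worldTier, s$regionTier,
                                    s$config))
  expect_false(r1@skipped)
  m1 <- speciesRunMetrics(r1, s$config)
  m2 <- speciesRunMetrics(r2, s$config)
  expect_equal(m1[sapply(m1, is.numeric)], m2[sapply(m2, is.numeric)],
               tolerance = 1e-9)
  expect_equal(layerValues(r1@regional@suitability),
               layerValues(r2@regional@suitability), tolerance = 1e-9)
  # tier variants follow the configured policy
  expect_identical(r1@occGlobal@variant, "certain_plus_NA")
  expect_identical(r1@occRegional@variant, "certain")
  # the regional maps live on the region grid, the weighting layer too
  expect_identical(r1@regional@suitability@grid, s$regionGrid)
  expect_identical(r1@projG@grid, s$regionGrid)
  expect_true(all(layerValues(r1@projG) >= 0 &
                  layerValues(r1@projG) <= 1, na.rm = TRUE))
})

test_that("species below the presence minimum are skipped, not fatal", {
  s <- miniSetup()
  few <- s$records[1:10, ]
  expect_message(res <- runSpecies(few, s$worldTier, s$regionTier,
                                   s$config), "skipping")
  expect_true(res@skipped)
  expect_match(res@reason, "presence cells")
  expect_identical(nrow(speciesRunMetrics(res, s$config)), 0L)
})

test_that("a saturated global projection zeroes all weights with a warning", {
  g <- gridSpec(0, 0, 0.25, 20, 20)
  st <- generateEnvironment(g, 2, 1, 3, seed = 9)
  cfg <- virtualSpeciesConfig("v", c(climate1 = 2),
                              prevalenceTarget = 0.3, nRecords = 300L,
                              pErrorRecords = 0, pMissingUncertainty = 0,
                              seed = 9)
  occ <- prepareOccurrences(sampleOccurrences(trueSuitability(st, cfg),
                                              cfg), g, "certain")
  ones <- rasterLayer(g, 1, "projG")
  expect_warning(
    ens <- fitEnsemble(presenceCells(occ), st,
                       quickEnsemble(nPseudoAbsences = 100L),
                       seed = 9, projG = ones),
    "all weights are zero")
  expect_s4_class(ens, "EnsemblePrediction")   # run completes regardless
})

test_that("variant comparison reports paired metrics and a 4-decimal distance", {
  s <- miniSetup()
  # force identical effective inputs: no NA uncertainties anywhere
  recs <- s$records
  recs$coordinateUncertaintyInMeters[
    is.na(recs$coordinateUncertaintyInMeters)] <- 100
  cmp <- suppressWarnings(compareVariants(recs, s$worldTier,
                                          s$regionTier, s$config))
  expect_identical(cmp$bhattacharyya, 0)       # identical runs coincide
  expect_identical(cmp$formatted, "0.0000")
  expect_setequal(unique(cmp$metrics$variantPolicy), c("A", "B"))
  expect_identical(nrow(cmp$metrics), 4L)      # 2 variants x 2 tiers
  # with NA-uncertainty records the variants genuinely differ
  cmp2 <- suppressWarnings(compareVariants(s$records, s$worldTier,
                                           s$regionTier, s$config))
  nG <- cmp2$metrics[cmp2$metrics$tier == "global_climatic", ]
  expect_gt(nG$n[nG$variantPolicy == "A"], nG$n[nG$variantPolicy == "B"])
  expect_gt(cmp2$bhattacharyya, 0)
})
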