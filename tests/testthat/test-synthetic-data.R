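test_that("simulation output is a pure function of the seed", {
  s1 <- simulateHistory(fixtureConfig(seed = 4))
  s2 <- simulateHistory(fixtureConfig(seed = 4))
  for (tip in names(s1$records)) {
    expect_equal(as.character(genomeSeq(s1$records[[tip]])),
                 as.character(genomeSeq(s2$records[[tip]])))
    expect_equal(features(s1$records[[tip]]), features(s2$records[[tip]]))
  }
  s3 <- simulateHistory(fixtureConfig(seed = 5))
  expect_false(identical(as.character(genomeSeq(s1$records[[1]])),
                         as.character(genomeSeq(s3$records[[1]]))))
})

test_that("fixture directories are byte-identical for the same seed", {
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  unlink(c(d1, d2), recursive = TRUE)
  makeFixtureSet(d1, seed = 2L)
  makeFixtureSet(d2, seed = 2L)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                 info = f)
})

test_that("a no-event history leaves every tip identical to the root", {
  cfg <- simulationConfig(seed = 6, nInversions = 0L, lossRate = 0,
                          mutRate = 0)
  sim <- simulateHistory(cfg)
  for (tip in names(sim$truth$tipOrders)) {
    expect_equal(breakpointCount(sim$truth$tipOrders[[tip]],
                                 sim$truth$rootOrder), 0L, info = tip)
    sc <- inferInversionScenario(sim$truth$tipOrders[[tip]],
                                 sim$truth$rootOrder)
    expect_equal(sc@distance, 0L)
  }
})

test_that("one planted repeat-spanning inversion flips only that tip to DR", {
  planted <- list(SelK = list(c(20L, 25L)))
  cfg <- simulationConfig(seed = 8, nInversions = 0L, lossRate = 0,
                          mutRate = 0, plantedEvents = planted)
  sim <- simulateHistory(cfg)
  expect_equal(unname(sim$truth$tipOrientation["SelK"]), "DR")
  others <- setdiff(names(sim$truth$tipOrientation), "SelK")
  expect_true(all(sim$truth$tipOrientation[others] == "IR"))
  rec <- sim$records[["SelK"]]
  expect_equal(classifyOrientation(findLargeRepeat(rec)), "DR")
})

test_that("planted fixture history is recovered by scenario inference", {
  sim <- simulateHistory(fixtureConfig(seed = 10))
  root <- sim$truth$rootOrder
  ## static lineage: zero events
  expect_equal(inferInversionScenario(root,
                                      sim$truth$tipOrders[["LycA"]]
                                      )@distance, 0L)
  ## single spanning inversion: IR -> DR
  scK <- inferInversionScenario(root, sim$truth$tipOrders[["SelK"]])
  expect_equal(scK@distance, 1L)
  expect_equal(scK@orientationTrajectory, c("IR", "DR"))
  ## relocation lineage: two overlapping spanning inversions, IR->DR->IR
  scI <- inferInversionScenario(root, sim$truth$tipOrders[["IsoA"]])
  expect_equal(scI@distance, 2L)
  expect_equal(scI@orientationTrajectory, c("IR", "DR", "IR"))
})

test_that("element counts are conserved minus planted losses", {
  cfg <- simulationConfig(seed = 15, nInversions = 1L, lossRate = 0.05,
                          mutRate = 0)
  sim <- simulateHistory(cfg)
  rootN <- length(blocks(sim$truth$rootOrder)) - 1L   # minus REP
  tree <- cfg$tree
  for (tip in names(sim$truth$tipOrders)) {
    lost <- unique(unlist(pathEvents(sim$truth, tree, tip, "losses")))
    expect_equal(length(blocks(sim$truth$tipOrders[[tip]])) - 1L,
                 rootN - length(lost), info = tip)
  }
})

test_that("full copy-correction keeps the two repeat copies identical", {
  cfg <- simulationConfig(seed = 16, conversionProb = 1,
                          rateReduction = 0.5)
  topo <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.25);")
  sim <- evolveSequences(topo, cfg, scCodons = 200L, repCodons = 400L,
                         ntSites = 10L)
  expect_identical(alignedSeqs(sim$rep), alignedSeqs(sim$repB))
})

test_that("without conversion or rate reduction the repeat matches SC", {
  ## r = 1, gamma = 0: copy A of the repeat is statistically
  ## indistinguishable from single-copy sequence
  pooledP <- function(aln) {
    m <- do.call(rbind, strsplit(alignedSeqs(aln), ""))
    mean(m[1, ] != m[2, ])
  }
  diffs <- replicate(3, NA_real_)
  for (k in 1:3) {
    cfg <- simulationConfig(seed = 100 + k, conversionProb = 0,
                            rateReduction = 1)
    topo <- ape::read.tree(text = "(A:0.4,B:0.4);")
    sim <- evolveSequences(topo, cfg, scCodons = 4000L,
                           repCodons = 4000L, ntSites = 10L)
    diffs[k] <- pooledP(sim$rep) / pooledP(sim$sc)
  }
  expect_lt(abs(mean(diffs) - 1), 0.1)
})

test_that("copy-corrected repeats diverge at rate r relative to SC", {
  pooledP <- function(aln) {
    m <- do.call(rbind, strsplit(alignedSeqs(aln), ""))
    mean(m[1, ] != m[2, ])
  }
  cfg <- simulationConfig(seed = 30, conversionProb = 1,
                          rateReduction = 0.3)
  topo <- ape::read.tree(text = "(A:0.5,B:0.5);")
  sim <- evolveSequences(topo, cfg, scCodons = 6000L, repCodons = 6000L,
                         ntSites = 10L)
  ## crude per-site divergence contrast; the model-based ratio is
  ## exercised in the acceptance suite
  expect_lt(abs(pooledP(sim$rep) / pooledP(sim$sc) - 0.3), 0.08)
})
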