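test_that("prior-only sampling reproduces an analytic calibration target", {
  # vanishing-diversification density has a closed exponential form, so this
  # doubles as a detailed-balance check against a normalised target
  psi <- 0.05
  dens <- singleCalibrationDensity(BDParams(1e-9, 0, psi),
                                   FossilRecord("f", 100), nReps = 5e4,
                                   seed = 1)
  tr <- twoTipTree(120)
  cal <- list(list(label = "root", node = 3L, density = dens))
  bd <- BDParams(0.06, 0.1, 0.02)
  trace <- samplePrior(tr, cal, bd,
                       MCMCConfig(iterations = 1e5, thinning = 2, seed = 2))
  ages <- traceSamples(trace, dropBurnin = TRUE)$rootAge
  expect_lt(ksAgainstDensity(ages, dens), 0.02)
  # and against the true analytic CDF, not just the tabulated one
  ks2 <- suppressWarnings(stats::ks.test(
    ages, function(q) stats::pexp(pmax(q - 100, 0), psi))$statistic)
  expect_lt(as.numeric(ks2), 0.02)
})

test_that("constraint mapping rejects non-monophyletic tip sets", {
  tr <- timeTree(ape::read.tree(text = "((A:10,B:10):10,(C:15,D:15):5);"))
  expect_error(mrcaNode(tr, c("A", "C")), "not monophyletic")
  expect_equal(mrcaNode(tr, c("A", "B")), 6L)
  expect_equal(mrcaNode(tr, c("A", "B", "C", "D")), 5L)
  expect_error(mrcaNode(tr, c("A", "Z")), "unknown tips")
})

test_that("topology and edge order constraints hold at every sample", {
  tr <- timeTree(ape::read.tree(text = "((A:10,B:10):10,(C:15,D:15):5);"))
  bd <- BDParams(0.06, 0.1, 0.02)
  cal <- buildCalibrations(tr, list(
    CladeConstraint("ab", c("A", "B"), FossilRecord("f1", 8))),
    bd, nReps = 5e3, seed = 3)
  trace <- samplePrior(tr, cal, bd,
                       MCMCConfig(iterations = 2e4, thinning = 10, seed = 4))
  s <- traceSamples(trace)
  expect_true(all(s$age_node5 > s$age_node6))
  expect_true(all(s$age_node5 > s$age_node7))
  expect_true(all(s$age_node6 > 0 & s$age_node7 > 0))
  expect_true(all(is.finite(s$logPosterior)))
  # topology is never altered
  expect_identical(trace@meta$topology, ape::write.tree(tr@phylo))
})

test_that("a zero-length alignment makes the posterior match the prior", {
  tr <- twoTipTree(120)
  dens <- singleCalibrationDensity(BDParams(1e-9, 0, 0.05),
                                   FossilRecord("f", 100), nReps = 3e4,
                                   seed = 5)
  cal <- list(list(label = "root", node = 3L, density = dens))
  bd <- BDParams(0.06, 0.1, 0.02)
  cfg <- MCMCConfig(iterations = 1e5, thinning = 2, seed = 6)
  emptyAln <- c(A = "", B = "")
  post <- samplePosterior(tr, emptyAln, SubstModel(), 1e-3, cal, bd, cfg)
  prior <- samplePrior(tr, cal, bd, cfg)
  a1 <- traceSamples(post, dropBurnin = TRUE)$rootAge
  a0 <- traceSamples(prior, dropBurnin = TRUE)$rootAge
  ks <- suppressWarnings(stats::ks.test(a1, a0)$statistic)
  expect_lt(as.numeric(ks), 0.02)
})

test_that("posterior recovers a known root age within the 95% HPD", {
  tr <- simulateTimeTree(6, rootAge = 100, seed = 7)
  model <- SubstModel()
  bdCal <- BDParams(1e-6, 0, 2)  # sharp calibration just below the root
  cal <- buildCalibrations(tr, list(
    CladeConstraint("root", tipNames(tr), FossilRecord("rf", 99.5))),
    bdCal, nReps = 2e4, seed = 8)
  aln <- simulateAlignment(tr, 1e-3, model, nSites = 5e3, seed = 9)
  bd <- BDParams(0.061, 0.1856, 0.01233)
  trace <- samplePosterior(tr, aln, model, 1e-3, cal, bd,
                           MCMCConfig(iterations = 2e4, thinning = 10,
                                      seed = 10))
  s <- traceSummary(trace)
  row <- s[s$parameter == "rootAge", ]
  expect_gt(100, row$hpdLow)
  expect_lt(100, row$hpdHigh)
})

test_that("alignment names must map onto the tree tips", {
  tr <- twoTipTree(50)
  expect_error(samplePosterior(tr, c(X = "ACGT", B = "ACGT"), SubstModel(),
                               1e-3, list(), BDParams(0.06, 0.1, 0.02),
                               MCMCConfig(iterations = 100, thinning = 1)),
               "taxon mapping")
})

test_that("bimodal calibrations are traversed by the chain", {
  bd <- BDParams(0.061, 0.1856, 0.01233)
  dens <- mixtureCalibrationDensity(
    FossilRecord("y", 100, weight = 0.5),
    FossilRecord("o", 220, weight = 0.5), bd, nReps = 4e4, seed = 11)
  modes <- findDensityModes(dens)
  expect_true(modes$bimodal)
  tr <- twoTipTree(150)
  cal <- list(list(label = "c", node = 3L, density = dens))
  trace <- samplePrior(tr, cal, bd,
                       MCMCConfig(iterations = 1e5, thinning = 2,
                                  seed = 12))
  ages <- traceSamples(trace, dropBurnin = TRUE)$rootAge
  sw <- countModeSwitches(ages, modes$valleyAge)
  expect_gt(sw / 9e4 * 1e6, 50)
  expect_lt(ksAgainstDensity(ages, dens), 0.02)
})
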