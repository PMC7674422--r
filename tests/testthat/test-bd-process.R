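test_that("rate reparameterisation inverts net diversification and turnover", {
  r <- deriveRates(0.06, 0)
  expect_equal(r$lambda, 0.06)
  expect_equal(r$mu, 0)
  r <- deriveRates(0.05, 0.5)
  expect_equal(r$lambda, 0.10)
  expect_equal(r$mu, 0.05)
  r <- deriveRates(0.041, 0.37)
  expect_equal(r$lambda - r$mu, 0.041)
  expect_equal(r$mu / r$lambda, 0.37)
  expect_error(deriveRates(0.05, 1), "turnover")
  expect_error(deriveRates(-0.1, 0.2), "invalid rate")
})

test_that("event-free process keeps one lineage and S(t) = t", {
  h <- simulateConditionedBD(0, 0, 50, nReps = 20, seed = 1)
  expect_true(all(h$N == 1))
  expect_true(all(h$S == 50))
})

test_that("conditioned mean lineage count matches analytic expectations", {
  # Yule: no conditioning effect, E[N] = exp(lambda t)
  h <- simulateConditionedBD(0.05, 0, 20, nReps = 4e4, seed = 2)
  se <- sd(h$N) / sqrt(nrow(h))
  expect_lt(abs(mean(h$N) - exp(1)), 3 * se)
  # with extinction the survival-conditioned mean is exp(rt) / P(survive),
  # cross-checked against the naive per-lineage oracle
  h <- simulateConditionedBD(0.1, 0.05, 30, nReps = 4e4, seed = 3)
  target <- exp(0.05 * 30) / bdSurvivalProbability(0.1, 0.05, 30)
  se <- sd(h$N) / sqrt(nrow(h))
  expect_lt(abs(mean(h$N) - target), 3 * se)
  set.seed(4)
  ho <- naiveConditionedSim(0.1, 0.05, 30, 3000)
  seo <- sqrt(sd(h$N)^2 / nrow(h) + sd(ho$N)^2 / nrow(ho))
  expect_lt(abs(mean(h$N) - mean(ho$N)), 3 * seo)
  expect_lt(abs(mean(h$S) - mean(ho$S)),
            3 * sqrt(sd(h$S)^2 / nrow(h) + sd(ho$S)^2 / nrow(ho)))
})

test_that("survival conditioning holds and acceptance matches analytic rate", {
  h <- simulateConditionedBD(0.08, 0.04, 40, nReps = 2e4, seed = 5)
  expect_true(all(h$N >= 1))
  expect_true(all(h$S >= 40 - 1e-9))
  expect_true(all(h$S[h$N == 1] >= 40))
  p <- bdSurvivalProbability(0.08, 0.04, 40)
  acc <- attr(h, "acceptance")
  se <- sqrt(p * (1 - p) / (2e4 / p))
  expect_lt(abs(acc - p), 3 * se)
})

test_that("identical seed and inputs reproduce identical histories", {
  a <- simulateConditionedBD(0.1, 0.02, 25, nReps = 50, seed = 42)
  b <- simulateConditionedBD(0.1, 0.02, 25, nReps = 50, seed = 42)
  expect_identical(a, b)
})

test_that("node-age prior on two tips reduces to the root prior", {
  tr <- twoTipTree(120)
  rp <- rootPrior("normal", mean = 300, sd = 0.1)
  expect_equal(bdNodeAgeLogDensity(tr, 0.1, 0, rp),
               dnorm(120, 300, 0.1, log = TRUE))
  expect_equal(bdNodeAgeLogDensity(tr, 0.1, 0, rootPrior("flat")), 0)
})

test_that("node-age prior is invariant under tip relabelling", {
  t1 <- timeTree(ape::read.tree(text = "((A:10,B:10):30,C:40);"))
  t2 <- timeTree(ape::read.tree(text = "((C:10,A:10):30,B:40);"))
  expect_equal(bdNodeAgeLogDensity(t1, 0.1, 0.03),
               bdNodeAgeLogDensity(t2, 0.1, 0.03))
})

test_that("invalid trees are rejected by the node-age prior", {
  expect_error(timeTree(ape::read.tree(text = "((A:5,B:10):30,C:40);")),
               "ultrametric")
  expect_error(timeTree(ape::read.tree(text = "((A:5,B:5,C:5):5,D:10);")),
               "polytomy")
})

test_that("prior-only MCMC marginal matches forward-simulated Yule node ages", {
  lambda <- 0.1
  Tage <- 10
  set.seed(11)
  orc <- yuleForwardCond(lambda, Tage, nTips = 3L, nAccept = 8000L)
  simAges <- vapply(orc$ages, `[[`, numeric(1L), 1L)
  tr <- timeTree(ape::read.tree(text = "((A:5,B:5):5,C:10);"))
  bd <- BDParams(lambda, 0, 0.01)
  trace <- samplePrior(tr, list(), bd,
                       MCMCConfig(iterations = 2e5, thinning = 2, seed = 12),
                       rootModel = rootPrior("normal", mean = Tage,
                                             sd = 0.005))
  mcmcAges <- traceSamples(trace, dropBurnin = TRUE)$age_node5
  ks <- suppressWarnings(stats::ks.test(mcmcAges, simAges)$statistic)
  expect_lt(as.numeric(ks), 0.02)
})

test_that("4-tip balanced-topology node ages match the simulation oracle", {
  lambda <- 0.12
  Tage <- 10
  set.seed(21)
  # node ages are iid given the tip count whatever the shape (checked via
  # the pectinate subset too), so all accepted trees can be pooled
  orc <- yuleForwardCond(lambda, Tage, nTips = 4L, nAccept = 2e4)
  pooled <- unlist(orc$ages)
  tr <- timeTree(ape::read.tree(
    text = "((A:4,B:4):6,(C:5,D:5):5);"))
  bd <- BDParams(lambda, 0, 0.01)
  trace <- samplePrior(tr, list(), bd,
                       MCMCConfig(iterations = 3e5, thinning = 3, seed = 22),
                       rootModel = rootPrior("normal", mean = Tage,
                                             sd = 0.005))
  s <- traceSamples(trace, dropBurnin = TRUE)
  mcmcPooled <- c(s$age_node6, s$age_node7)
  ks <- suppressWarnings(stats::ks.test(mcmcPooled, pooled)$statistic)
  expect_lt(as.numeric(ks), 0.02)
})
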