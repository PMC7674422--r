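gtrTestModel <- function() {
  SubstModel(rates = c(1, 2, 1.5, 0.8, 3, 1),
             baseFreqs = c(0.3, 0.2, 0.25, 0.25), gammaShape = 0.7,
             nCategories = 3L)
}

test_that("pruning equals exhaustive enumeration on small trees", {
  for (n in c(3L, 4L)) {
    tr <- simulateTimeTree(n, rootAge = 50, seed = n)
    model <- gtrTestModel()
    aln <- simulateAlignment(tr, 2e-3, model, nSites = 3, seed = n + 10L)
    expect_lt(abs(felsensteinLogLik(aln, tr, 2e-3, model) -
                    enumLogLik(aln, tr, 2e-3, model)), 1e-10)
  }
})

test_that("pruning agrees with phangorn's implementation", {
  tr <- simulateTimeTree(5, rootAge = 80, seed = 31)
  model <- gtrTestModel()
  aln <- simulateAlignment(tr, 1e-3, model, nSites = 200, seed = 32)
  ours <- felsensteinLogLik(aln, tr, 1e-3, model)
  chars <- do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
  rownames(chars) <- names(aln)
  dat <- phangorn::phyDat(chars, type = "DNA")
  fit <- phangorn::pml(tr@phylo, dat, bf = model@baseFreqs,
                       Q = model@rates, shape = model@gammaShape, k = 3,
                       rate = 1e-3)
  expect_equal(ours, fit$logLik, tolerance = 1e-8)
})

test_that("zero-time limit gives log equilibrium frequency", {
  phy <- ape::read.tree(text = "(A:1e-9,B:1e-9);")
  tr <- timeTree(phy)
  model <- SubstModel(baseFreqs = c(0.4, 0.3, 0.2, 0.1), nCategories = 1L)
  aln <- c(A = "A", B = "A")
  ll <- felsensteinLogLik(aln, tr, 1e-9, model)
  expect_equal(ll, log(0.4), tolerance = 1e-6)
})

test_that("Jukes-Cantor two-taxon case matches the closed form", {
  tr <- twoTipTree(10)
  model <- SubstModel(nCategories = 1L)
  rate <- 0.01
  dist <- 2 * 10 * rate  # total path length in expected substitutions
  pSame <- 1 / 4 + 3 / 4 * exp(-4 / 3 * dist)
  pDiff <- 1 / 4 - 1 / 4 * exp(-4 / 3 * dist)
  expect_lt(abs(felsensteinLogLik(c(A = "A", B = "A"), tr, rate, model) -
                  log(0.25 * pSame)), 1e-10)
  expect_lt(abs(felsensteinLogLik(c(A = "A", B = "G"), tr, rate, model) -
                  log(0.25 * pDiff)), 1e-10)
})

test_that("likelihood is invariant to site order and taxon order", {
  tr <- simulateTimeTree(4, rootAge = 60, seed = 41)
  model <- gtrTestModel()
  aln <- as.character(simulateAlignment(tr, 1e-3, model, nSites = 50,
                                        seed = 42))
  ll <- felsensteinLogLik(aln, tr, 1e-3, model)
  perm <- sample(nchar(aln[[1L]]))
  shuffled <- vapply(aln, function(s)
    paste(strsplit(s, "")[[1L]][perm], collapse = ""), character(1L))
  expect_equal(felsensteinLogLik(shuffled, tr, 1e-3, model), ll)
  expect_equal(felsensteinLogLik(rev(aln), tr, 1e-3, model), ll)
})

test_that("missing data and unknown characters are handled", {
  tr <- twoTipTree(10)
  model <- SubstModel(nCategories = 1L)
  # an all-missing taxon contributes nothing: likelihood is the marginal
  ll <- felsensteinLogLik(c(A = "A", B = "N"), tr, 0.01, model)
  expect_equal(ll, log(0.25), tolerance = 1e-10)
  expect_error(felsensteinLogLik(c(A = "X", B = "A"), tr, 0.01, model),
               "parse error")
  expect_error(felsensteinLogLik(c(A = "AA", B = "AA"),
                                 simulateTimeTree(3, 10, seed = 1), 0.01,
                                 model),
               "taxon mapping")
})

test_that("single-category model equals the large-shape gamma limit", {
  tr <- simulateTimeTree(4, rootAge = 60, seed = 51)
  aln <- simulateAlignment(tr, 1e-3, SubstModel(), nSites = 100, seed = 52)
  m1 <- SubstModel(nCategories = 1L)
  mInf <- SubstModel(gammaShape = 1e9, nCategories = 4L)
  expect_equal(felsensteinLogLik(aln, tr, 1e-3, m1),
               felsensteinLogLik(aln, tr, 1e-3, mInf), tolerance = 1e-6)
})

test_that("zero clock rate copies the root state to every tip", {
  tr <- simulateTimeTree(5, rootAge = 100, seed = 61)
  aln <- as.character(simulateAlignment(tr, 0, SubstModel(), nSites = 200,
                                        seed = 62))
  expect_length(unique(unname(aln)), 1L)
})

test_that("simulated base composition converges to the model frequencies", {
  tr <- twoTipTree(1)
  model <- SubstModel(baseFreqs = c(0.4, 0.3, 0.2, 0.1), nCategories = 1L)
  aln <- as.character(simulateAlignment(tr, 1, model, nSites = 5e4,
                                        seed = 63))
  chars <- strsplit(aln[[1L]], "")[[1L]]
  for (i in 1:4) {
    p <- model@baseFreqs[i]
    frac <- mean(chars == c("A", "C", "G", "T")[i])
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 5e4))
  }
})

test_that("saturated branches decouple the tip sequences", {
  tr <- twoTipTree(100)  # 2 * 100 expected substitutions at rate 1
  model <- SubstModel(nCategories = 1L)
  aln <- as.character(simulateAlignment(tr, 1, model, nSites = 2e4,
                                        seed = 64))
  a <- strsplit(aln[["A"]], "")[[1L]]
  b <- strsplit(aln[["B"]], "")[[1L]]
  joint <- mean(a == "A" & b == "A")
  indep <- mean(a == "A") * mean(b == "A")
  expect_lt(abs(joint - indep), 3 * sqrt(indep * (1 - indep) / 2e4))
})

test_that("true parameters beat perturbed parameters on simulated data", {
  tr <- simulateTimeTree(5, rootAge = 50, seed = 71)
  model <- SubstModel()
  wins <- 0L
  for (r in 1:20) {
    aln <- simulateAlignment(tr, 1e-3, model, nSites = 1e4, seed = 100 + r)
    llTrue <- felsensteinLogLik(aln, tr, 1e-3, model)
    llPert <- felsensteinLogLik(aln, tr, 2e-3, model)
    if (llTrue > llPert) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("rate-time confounding leaves the likelihood surface unchanged", {
  tr <- simulateTimeTree(5, rootAge = 80, seed = 81)
  model <- gtrTestModel()
  aln <- simulateAlignment(tr, 1e-3, model, nSites = 300, seed = 82)
  half <- setTreeAges(tr, nodeAges(tr) / 2)
  expect_equal(felsensteinLogLik(aln, tr, 1e-3, model),
               felsensteinLogLik(aln, half, 2e-3, model),
               tolerance = 1e-10)
})
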