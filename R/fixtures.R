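#' Locate the modes and inter-mode valley of a calibration density
#'
#' Smooths the tabulated density with a short running mean, finds local
#' maxima above 1% of the global maximum, and (for two-fossil mixtures)
#' reports the minimum between the two largest modes. Used to flag
#' bimodality and to define the valley age that mode-switch counting
#' crosses.
#'
#' @param density a \code{\linkS4class{CalibrationDensity}}.
#' @param window running-mean half-width in grid points.
#' @return list: \code{modes} (ages of local maxima, descending density),
#'   \code{valleyAge} (NA when unimodal), \code{bimodal} (logical).
#' @export
findDensityModes <- function(density, window = 7L) {
  g <- density@ageGrid
  f <- density@densityValues
  k <- 2L * window + 1L
  sm <- stats::filter(f, rep(1 / k, k), sides = 2L)
  sm[is.na(sm)] <- f[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  isMax <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
               sm[2:(n - 1)] >= sm[3:n], FALSE)
  isMax[1L] <- sm[1L] > sm[2L]
  isMax[n] <- sm[n] > sm[n - 1L]
  isMax <- isMax & sm > 0.01 * max(sm)
  idx <- which(isMax)
  # merge plateau/adjacent maxima closer than the smoothing window
  if (length(idx) > 1L) {
    keep <- c(TRUE, diff(idx) > k)
    idx <- idx[keep]
  }
  idx <- idx[order(sm[idx], decreasing = TRUE)]
  if (length(idx) < 2L)
    return(list(modes = g[idx], valleyAge = NA_real_, bimodal = FALSE))
  i1 <- min(idx[1:2]); i2 <- max(idx[1:2])
  vi <- i1 + which.min(sm[i1:i2]) - 1L
  bimodal <- sm[vi] < 0.98 * min(sm[i1], sm[i2])
  list(modes = g[idx], valleyAge = if (bimodal) g[vi] else NA_real_,
       bimodal = bimodal)
}

#' Count crossings of the inter-mode valley in a trace
#'
#' A switch is a pair of consecutive retained samples on opposite sides of
#' the valley age.
#'
#' @param series sampled ages (thinned trace column).
#' @param valleyAge valley age (Ma).
#' @return number of crossings.
#' @export
countModeSwitches <- function(series, valleyAge) {
  if (is.na(valleyAge)) return(0L)
  side <- series > valleyAge
  sum(side[-1L] != side[-length(side)])
}

#' Bimodality and convergence experiment with two simulated fossils
#'
#' For each temporal separation, places two point-age fossils with equal
#' weights that distance apart, builds the two-fossil mixture calibration
#' density, runs prior-only MCMC on a minimal two-tip tree whose root is the
#' calibrated node (flat root prior; no other constraints), and reports the
#' Kolmogorov-Smirnov distance between the sampled ages and the calibration
#' density together with the number of inter-mode switches.
#'
#' @param separations temporal distances between the two fossils (Myr).
#' @param bd a \code{\link{BDParams}}; defaults to the midpoints of the
#'   teleost rate ranges (psi 0.01233, d 0.061, eps 0.1856).
#' @param config an \code{\link{MCMCConfig}}.
#' @param youngerAge age (Ma) of the younger simulated fossil.
#' @param nRepsDensity Monte-Carlo replicates for each density.
#' @return data.frame: separation, ks, switches, iterations, bimodal.
#' @export
bimodalityExperiment <- function(separations = c(30, 60, 90, 120),
                                 bd = BDParams(0.061, 0.1856, 0.01233),
                                 config = MCMCConfig(iterations = 2e5,
                                                     thinning = 2,
                                                     seed = 1L),
                                 youngerAge = 100, nRepsDensity = 1e5) {
  stopifnot(all(separations >= 0))
  out <- lapply(separations, function(sep) {
    young <- FossilRecord("sim_younger", youngerAge, weight = 0.5)
    old <- FossilRecord("sim_older", youngerAge + sep, weight = 0.5)
    dens <- if (sep > 0) {
      mixtureCalibrationDensity(young, old, bd, nReps = nRepsDensity,
                                seed = config@seed)
    } else {
      old@weight <- 1 - young@weight
      mixtureCalibrationDensity(young, old, bd, nReps = nRepsDensity,
                                seed = config@seed)
    }
    tipAge <- max(densityQuantile(dens, 0.5), 1)
    tr <- timeTree(ape::read.tree(
      text = sprintf("(A:%.6f,B:%.6f);", tipAge, tipAge)))
    cal <- list(list(label = "calibrated", node = 3L, density = dens))
    trace <- samplePrior(tr, cal, bd, config)
    ages <- traceSamples(trace, dropBurnin = TRUE)$rootAge
    ks <- suppressWarnings(stats::ks.test(
      ages, function(q) densityCDF(dens, q))$statistic)
    modes <- findDensityModes(dens)
    data.frame(separation = sep, ks = as.numeric(ks),
               switches = countModeSwitches(ages, modes$valleyAge),
               retained = length(ages),
               iterations = config@iterations *
                 (1 - config@burninFraction),
               bimodal = modes$bimodal)
  })
  do.call(rbind, out)
}

#' Generate a planted-violation marker-filter fixture
#'
#' Builds an exon metric table (and optionally alignments) in which exactly
#' the requested numbers of violations are planted for each filter step,
#' together with the FilterReport the cascade is expected to produce. The
#' generators are self-verifying: the expected report always matches the
#' filters' actual report on the generated data.
#'
#' @param nGenes number of genes.
#' @param exonsPerGene exons per gene (>= 4 leaves headroom for per-exon
#'   removals without collapsing the gene).
#' @param nSpecies ingroup species per exon.
#' @param violations named list of planted counts: \code{bitscore},
#'   \code{dnds}, \code{missingExons} (sequence cascade); \code{codons},
#'   \code{shortAlignments}, \code{gcAlignments}, \code{structureGenes}
#'   (alignment cascade).
#' @param seed RNG seed; identical spec + seed give identical fixtures.
#' @return list: \code{table}, \code{alignments}, \code{exonInfo},
#'   \code{entropyScores}, \code{expectedSequenceReport},
#'   \code{expectedAlignmentReport}.
#' @export
generateMarkerFixture <- function(nGenes = 4, exonsPerGene = 4,
                                  nSpecies = 15,
                                  violations = list(), seed = 1L) {
  v <- list(bitscore = 0L, dnds = 0L, missingExons = 0L, codons = 0L,
            shortAlignments = 0L, gcAlignments = 0L, structureGenes = 0L)
  v[names(violations)] <- lapply(violations, as.integer)
  if (any(unlist(v) < 0)) stop("spec error: violation counts must be >= 0")
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(nGenes))
  tab <- expand.grid(exon = sprintf("e%02d", seq_len(exonsPerGene)),
                     gene = genes, species = sprintf("sp%02d",
                                                     seq_len(nSpecies)),
                     stringsAsFactors = FALSE)
  tab <- tab[, c("gene", "exon", "species")]
  tab$bitscore <- round(stats::runif(nrow(tab), 95, 100), 2)
  tab$bitscoreThreshold <- 50
  tab$dnds <- round(stats::runif(nrow(tab), 0.02, 0.15), 3)
  tab$gc <- round(stats::runif(nrow(tab), 0.4, 0.6), 3)
  tab$present <- TRUE
  tab$length <- 300L

  exKey <- unique(tab[, c("gene", "exon")])
  nExons <- nrow(exKey)
  if (v$missingExons > nExons)
    stop("spec error: more missing-exon violations than exons")
  missIdx <- seq_len(v$missingExons)  # first exons carry the missing plant
  maxMissing <- 10L
  if (nSpecies <= maxMissing + 1L && v$missingExons > 0)
    stop("spec error: need more species than maxMissing + 1")
  okExons <- setdiff(seq_len(nExons), missIdx)
  capacity <- length(okExons) * maxMissing
  if (v$bitscore + v$dnds > capacity)
    stop("spec error: violation count exceeds per-exon removal capacity")

  rowKey <- paste(tab$gene, tab$exon)
  exNames <- paste(exKey$gene, exKey$exon)
  for (i in missIdx) {
    rows <- which(rowKey == exNames[i])
    tab$present[rows[seq_len(maxMissing + 1L)]] <- FALSE
  }
  # distribute sequence-level victims round-robin over unaffected exons
  victims <- function(k, offset) {
    picks <- integer(0)
    slot <- 0L
    while (length(picks) < k) {
      ex <- okExons[(slot %% length(okExons)) + 1L]
      rows <- which(rowKey == exNames[ex] & tab$present)
      used <- (slot %/% length(okExons))
      picks <- c(picks, rows[offset + used])
      slot <- slot + 1L
    }
    picks
  }
  if (v$bitscore > 0) {
    rows <- victims(v$bitscore, 1L)
    tab$bitscore[rows] <- 80  # below 90% of the ~100 best
  }
  if (v$dnds > 0) {
    rows <- victims(v$dnds, 4L)  # disjoint from bitscore victims
    tab$dnds[rows] <- 0.40
  }
  presentRows <- sum(tab$present)
  expSeq <- rbind(
    .reportRow("relative_bitscore", "sequences", presentRows, v$bitscore),
    .reportRow("dnds", "sequences", presentRows - v$bitscore, v$dnds),
    .reportRow("missing_sequences", "exons", nExons, v$missingExons))

  fix <- .alignmentFixture(v, seed)
  list(table = tab, alignments = fix$alignments, exonInfo = fix$exonInfo,
       entropyScores = fix$entropyScores, expectedSequenceReport = expSeq,
       expectedAlignmentReport = fix$expected)
}

# alignment-cascade fixture: dedicated genes per planted violation class
.alignmentFixture <- function(v, seed) {
  set.seed(seed + 1L)
  nSeq <- 8L
  cleanAln <- function(nCodons, species = sprintf("sp%02d", seq_len(nSeq))) {
    base <- paste(rep(c("ACG", "TTC", "GAT"), length.out = nCodons),
                  collapse = "")
    stats::setNames(rep(base, length(species)), species)
  }
  alignments <- list(); exonInfo <- NULL; entropy <- list()
  addGene <- function(gene, nExons, nCodons = 100L, startStep = 2000L) {
    for (i in seq_len(nExons)) {
      nm <- sprintf("%s:e%02d", gene, i)
      alignments[[nm]] <<- cleanAln(nCodons)
      exonInfo <<- rbind(exonInfo, data.frame(
        gene = gene, exon = sprintf("e%02d", i),
        start = (i - 1L) * startStep, end = (i - 1L) * startStep + 300L))
      entropy[[nm]] <<- rep(0.1, nCodons)
    }
  }
  addGene("ga", 4L)  # always-clean gene
  nMaskCarrier <- if (v$codons > 0) 1L else 0L
  if (nMaskCarrier) {
    addGene("gm", 4L, nCodons = 100L + v$codons)
    # plant codons with >20% missing data in the first exon
    a <- alignments[["gm:e01"]]
    chars <- do.call(rbind, strsplit(a, "", fixed = TRUE))
    for (k in seq_len(v$codons)) {
      cols <- (3L * (k - 1L) + 1L):(3L * k)
      chars[seq_len(ceiling(0.25 * nSeq)), cols[1L]] <- "N"
    }
    alignments[["gm:e01"]] <- stats::setNames(
      apply(chars, 1L, paste, collapse = ""), names(a))
  }
  for (k in seq_len(v$shortAlignments)) {
    g <- sprintf("gs%d", k)
    addGene(g, 4L)
    alignments[[sprintf("%s:e01", g)]] <-
      cleanAln(49L)  # 147 bp < 150 after zero masking
    entropy[[sprintf("%s:e01", g)]] <- rep(0.1, 49L)
  }
  for (k in seq_len(v$gcAlignments)) {
    g <- sprintf("gg%d", k)
    addGene(g, 4L)
    nm <- sprintf("%s:e01", g)
    a <- alignments[[nm]]
    gcRich <- paste(rep("GGC", 100L), collapse = "")
    atRich <- paste(rep("ATA", 100L), collapse = "")
    alignments[[nm]] <- stats::setNames(
      c(rep(gcRich, nSeq / 2), rep(atRich, nSeq / 2)), names(a))
  }
  for (k in seq_len(v$structureGenes)) {
    addGene(sprintf("gw%d", k), 3L, startStep = 60000L)  # span 120 kb
  }
  totCod <- sum(vapply(alignments, function(a) nchar(a[[1L]]) %/% 3L,
                       integer(1L)))
  nAln <- length(alignments)
  structLoss <- 3L * v$structureGenes
  expected <- rbind(
    .reportRow("codon_mask", "codons", totCod, v$codons),
    .reportRow("min_length", "alignments", nAln, v$shortAlignments),
    .reportRow("gc_sd", "alignments", nAln - v$shortAlignments,
               v$gcAlignments),
    .reportRow("gene_structure", "alignments",
               nAln - v$shortAlignments - v$gcAlignments, structLoss))
  list(alignments = alignments, exonInfo = exonInfo,
       entropyScores = entropy, expected = expected)
}
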