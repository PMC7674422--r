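#' Attach calibration densities to clade constraints on a fixed tree
#'
#' Maps each constraint's tip set to its node, builds the single-fossil or
#' two-fossil mixture calibration density, and returns the list the samplers
#' consume. Densities are computed once here and only interpolated during
#' MCMC.
#'
#' @param tree a \code{TimeTree}.
#' @param constraints list of \code{\link{CladeConstraint}} objects.
#' @param bd a \code{\link{BDParams}}.
#' @param nReps Monte-Carlo replicates per density.
#' @param seed RNG seed.
#' @param gridSpec passed through to the density constructors.
#' @return list of entries with elements \code{label}, \code{node},
#'   \code{density}.
#' @export
buildCalibrations <- function(tree, constraints, bd, nReps = 1e5,
                              seed = NULL, gridSpec = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(constraints, function(cc) {
    stopifnot(is(cc, "CladeConstraint"))
    node <- mrcaNode(tree, cc@tipSet)
    dens <- if (length(cc@fossils) == 1L) {
      singleCalibrationDensity(bd, cc@fossils[[1L]], gridSpec = gridSpec,
                               nReps = nReps)
    } else {
      mixtureCalibrationDensity(cc@fossils[[1L]], cc@fossils[[2L]], bd,
                                gridSpec = gridSpec, nReps = nReps)
    }
    list(label = cc@cladeLabel, node = node, density = dens)
  })
}

# fast linear interpolation of a tabulated log density; -Inf off support
.makeLogInterp <- function(density) {
  g <- density@ageGrid
  f <- density@densityValues
  force(g); force(f)
  function(x) {
    if (x < g[1L] || x > g[length(g)]) return(-Inf)
    i <- findInterval(x, g)
    if (i >= length(g)) i <- length(g) - 1L
    w <- (x - g[i]) / (g[i + 1L] - g[i])
    v <- (1 - w) * f[i] + w * f[i + 1L]
    if (v <= 0) -Inf else log(v)
  }
}

#' Sample node ages from the prior on a fixed topology
#'
#' Metropolis-Hastings sampling of internal node ages under the birth-death
#' node-age prior times the clade calibration densities, with the topology
#' held fixed. Four proposal operators act on ages: a uniform node slide
#' within the bracket (oldest child, parent), a subtree age scaler, a
#' root scaler, and a uniform independence redraw over a calibrated node's
#' support (the latter lets the chain jump between the modes of bimodal
#' mixture densities). Scalers carry the usual |s|^k Hastings correction.
#'
#' @param tree a \code{TimeTree}; its ages are the starting state.
#' @param calibrations output of \code{\link{buildCalibrations}} (possibly
#'   empty).
#' @param bd a \code{\link{BDParams}}; range midpoints set the birth-death
#'   prior's speciation and extinction rates.
#' @param config an \code{\link{MCMCConfig}}.
#' @param rootModel a \code{\link{rootPrior}} on the root age.
#' @return an \code{\linkS4class{MCMCTrace}}.
#' @examples
#' tr <- timeTree(ape::read.tree(text = "(A:100,B:100);"))
#' bd <- BDParams(0.06, 0.1, 0.02)
#' cal <- buildCalibrations(tr, list(CladeConstraint("root", c("A", "B"),
#'   FossilRecord("f", 90))), bd, nReps = 5e3, seed = 1)
#' trace <- samplePrior(tr, cal, bd, MCMCConfig(iterations = 2e3, seed = 1))
#' @export
samplePrior <- function(tree, calibrations = list(), bd, config,
                        rootModel = rootPrior("flat")) {
  .runMCMC(tree, calibrations, bd, config, rootModel, likFun = NULL)
}

#' Sample node ages from the posterior under a strict-clock likelihood
#'
#' Adds the Felsenstein pruning likelihood of a nucleotide alignment
#' (GTR + discrete gamma, strict clock) to the prior of
#' \code{\link{samplePrior}}, plus a clock-rate scale operator with a broad
#' log-uniform prior on the clock rate.
#'
#' @inheritParams samplePrior
#' @param alignment sequences named by tree tips (DNAStringSet or named
#'   character vector). A zero-length alignment (0 sites) contributes a
#'   constant likelihood, so the trace matches \code{samplePrior}.
#' @param model a \code{\link{SubstModel}}.
#' @param clockRate starting clock rate (substitutions/site/Myr), > 0.
#' @param clockBounds log-uniform prior bounds on the clock rate.
#' @return an \code{\linkS4class{MCMCTrace}} with a \code{clockRate} column.
#' @export
samplePosterior <- function(tree, alignment, model, clockRate,
                            calibrations = list(), bd, config,
                            rootModel = rootPrior("flat"),
                            clockBounds = clockRate * c(1e-3, 1e3)) {
  stopifnot(clockRate > 0)
  m <- .alignmentMatrix(alignment)
  if (ncol(m) == 0L) {
    likFun <- function(ages, rate) 0
  } else {
    phy <- tree@phylo
    missing <- setdiff(phy$tip.label, rownames(m))
    if (length(missing))
      stop("taxon mapping error: no sequence for ",
           paste(missing, collapse = ", "))
    m <- m[phy$tip.label, , drop = FALSE]
    pat <- .sitePatterns(m)
    po <- ape::reorder.phylo(phy, "postorder")
    eg <- .gtrEigen(model)
    rates <- .gammaRates(model@gammaShape, model@nCategories)
    edge <- po$edge
    nTip <- length(phy$tip.label)
    likFun <- function(ages, rate) {
      blen <- (ages[edge[, 1L]] - ages[edge[, 2L]]) * rate
      pruning_loglik_cpp(edge, blen, pat$patterns, pat$weights,
                         model@baseFreqs, eg$U, eg$Uinv, eg$eval, rates,
                         nTip)
    }
  }
  .runMCMC(tree, calibrations, bd, config, rootModel, likFun = likFun,
           clockRate = clockRate, clockBounds = clockBounds)
}

.runMCMC <- function(tree, calibrations, bd, config, rootModel, likFun,
                     clockRate = NULL, clockBounds = NULL) {
  stopifnot(is(tree, "TimeTree"), is(bd, "BDParams"), is(config, "MCMCConfig"))
  validObject(config)
  set.seed(config@seed)
  phy <- tree@phylo
  nTip <- length(phy$tip.label)
  nNode <- phy$Nnode
  root <- nTip + 1L
  internals <- root:(nTip + nNode)
  maps <- .treeMaps(phy)
  edge <- phy$edge
  dMid <- mean(bd@netDiversification)
  epsMid <- mean(bd@turnover)
  lm <- deriveRates(dMid, epsMid)
  if (lm$lambda <= lm$mu)
    stop("birth-death node-age prior needs lambda > mu")

  calNodes <- vapply(calibrations, `[[`, integer(1L), "node")
  calInterp <- lapply(calibrations, function(x) .makeLogInterp(x$density))
  calSupport <- lapply(calibrations, function(x) range(x$density@ageGrid))

  # internal descendants of each internal node (for the subtree scaler)
  descInternal <- lapply(internals, function(v) {
    out <- integer(0)
    stack <- maps$children[[v]]
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      if (x > nTip) {
        out <- c(out, x)
        stack <- c(stack, maps$children[[x]])
      }
    }
    out
  })
  names(descInternal) <- as.character(internals)

  ages <- tree@nodeAges
  # start calibrated nodes at their density medians, then raise any parent
  # below its children so the initial state is feasible
  for (i in seq_along(calNodes))
    ages[calNodes[i]] <- densityQuantile(calibrations[[i]]$density, 0.5)
  repeat {
    childMax <- vapply(internals, function(v)
      max(ages[maps$children[[v]]]), numeric(1L))
    bad <- which(ages[internals] <= childMax)
    if (!length(bad)) break
    ages[internals[bad]] <- childMax[bad] * 1.0001 + 1e-6
  }

  logTarget <- function(ages, rate) {
    if (any(ages[edge[, 1L]] <= ages[edge[, 2L]])) return(-Inf)
    lp <- .bdAgesLogDensityCore(ages[internals], lm$lambda, lm$mu)
    if (!is.finite(lp)) return(lp)
    lp <- lp + .rootLogDensity(rootModel, ages[root])
    for (i in seq_along(calNodes)) {
      lp <- lp + calInterp[[i]](ages[calNodes[i]])
      if (!is.finite(lp)) return(lp)
    }
    if (!is.null(likFun)) {
      if (rate < clockBounds[1L] || rate > clockBounds[2L]) return(-Inf)
      lp <- lp - log(rate) + likFun(ages, rate)  # log-uniform clock prior
    }
    lp
  }

  rate <- clockRate
  lp <- logTarget(ages, rate)
  if (!is.finite(lp))
    stop("could not find a feasible starting state; supply a starting tree ",
         "compatible with the calibrations")

  opNames <- c("nodeSlide", "subtreeScale", "rootScale", "uniformRedraw")
  w <- config@operatorWeights[opNames]
  if (!is.null(likFun)) {
    opNames <- c(opNames, "clockScale")
    w <- c(w, clockScale = max(1, sum(w) / 5))
  }
  w <- w / sum(w)
  lf <- log(config@scaleFactor)
  redrawNodes <- if (length(calNodes)) calNodes else root
  redrawWin <- if (length(calNodes)) calSupport else
    list(c(0, 3 * ages[root]))

  nOut <- floor(config@iterations / config@thinning)
  ageCols <- matrix(NA_real_, nOut, nNode)
  lpCol <- numeric(nOut)
  rateCol <- if (!is.null(likFun)) numeric(nOut) else NULL
  prop <- acc <- stats::setNames(numeric(length(opNames)), opNames)

  for (it in seq_len(config@iterations)) {
    op <- sample.int(length(opNames), 1L, prob = w)
    newAges <- ages
    newRate <- rate
    logH <- 0
    ok <- TRUE
    nm <- opNames[op]
    if (nm == "nodeSlide") {
      v <- internals[sample.int(nNode, 1L)]
      if (v == root) {
        cand <- ages[root] + stats::runif(1L, -config@slideWindow,
                                          config@slideWindow)
        if (cand <= max(ages[maps$children[[root]]])) ok <- FALSE
        newAges[root] <- cand
      } else {
        lo <- max(ages[maps$children[[v]]])
        hi <- ages[maps$parent[v]]
        newAges[v] <- stats::runif(1L, lo, hi)
      }
    } else if (nm == "subtreeScale") {
      v <- internals[sample.int(nNode, 1L)]
      grp <- c(v, descInternal[[as.character(v)]])
      s <- exp(stats::runif(1L, -lf, lf))
      newAges[grp] <- ages[grp] * s
      logH <- length(grp) * log(s)
    } else if (nm == "rootScale") {
      s <- exp(stats::runif(1L, -lf, lf))
      newAges[internals] <- ages[internals] * s
      logH <- nNode * log(s)
    } else if (nm == "uniformRedraw") {
      k <- sample.int(length(redrawNodes), 1L)
      win <- redrawWin[[k]]
      newAges[redrawNodes[k]] <- stats::runif(1L, win[1L], win[2L])
    } else {  # clockScale
      s <- exp(stats::runif(1L, -lf, lf))
      newRate <- rate * s
      logH <- log(s)
    }
    prop[nm] <- prop[nm] + 1
    if (ok) {
      lpNew <- logTarget(newAges, newRate)
      if (is.finite(lpNew) &&
          log(stats::runif(1L)) < lpNew - lp + logH) {
        ages <- newAges; rate <- newRate; lp <- lpNew
        acc[nm] <- acc[nm] + 1
      }
    }
    if (it %% config@thinning == 0L) {
      j <- it %/% config@thinning
      ageCols[j, ] <- ages[internals]
      lpCol[j] <- lp
      if (!is.null(rateCol)) rateCol[j] <- rate
    }
  }

  samples <- data.frame(iteration = seq_len(nOut) * config@thinning,
                        logPosterior = lpCol)
  samples$rootAge <- ageCols[, 1L]
  for (j in seq_len(nNode))
    samples[[paste0("age_node", internals[j])]] <- ageCols[, j]
  if (!is.null(rateCol)) samples$clockRate <- rateCol
  meta <- list(
    calibratedNodes = stats::setNames(
      calNodes, vapply(calibrations, `[[`, character(1L), "label")),
    acceptance = ifelse(prop > 0, acc / prop, NA_real_),
    lambda = lm$lambda, mu = lm$mu, topology = ape::write.tree(phy))
  new("MCMCTrace", samples = samples, thinning = config@thinning,
      burninFraction = config@burninFraction, seed = config@seed,
      meta = meta)
}
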