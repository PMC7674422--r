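#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib fossilcal, .registration = TRUE
NULL

.range2 <- function(x, what) {
  if (!is.numeric(x) || !length(x) %in% c(1L, 2L) || anyNA(x))
    stop(what, " must be a numeric point value or a [min, max] range")
  x <- as.numeric(x)
  if (length(x) == 1L) x <- c(x, x)
  if (x[1L] > x[2L]) stop(what, ": range min exceeds max")
  x
}

#' Birth-death and fossil-sampling parameters
#'
#' Container for the three rates that shape a clade-age calibration density:
#' the net diversification rate d = lambda - mu, the turnover eps = mu/lambda,
#' and the fossil sampling rate psi (preserved-and-discovered fossil
#' occurrences per lineage per Myr). Each may be a point value or a
#' \code{c(min, max)} range; ranges are marginalised over uniformly when
#' densities are computed.
#'
#' @slot netDiversification numeric(2), min/max of d (per lineage per Myr).
#' @slot turnover numeric(2), min/max of eps, in [0, 1).
#' @slot samplingRate numeric(2), min/max of psi (per lineage per Myr).
#' @export
setClass("BDParams", representation(
  netDiversification = "numeric",
  turnover = "numeric",
  samplingRate = "numeric"
))

setValidity("BDParams", function(object) {
  d <- object@netDiversification
  e <- object@turnover
  p <- object@samplingRate
  if (length(d) != 2L || length(e) != 2L || length(p) != 2L)
    return("rates must be stored as length-2 [min, max] vectors")
  if (d[1L] < 0) return("net diversification must be >= 0")
  if (e[1L] < 0 || e[2L] >= 1) return("turnover must lie in [0, 1)")
  if (p[1L] <= 0) return("fossil sampling rate must be > 0")
  if (any(c(d[1L] > d[2L], e[1L] > e[2L], p[1L] > p[2L])))
    return("range min exceeds max")
  TRUE
})

#' @param netDiversification point or \code{c(min, max)} for d.
#' @param turnover point or \code{c(min, max)} for eps.
#' @param samplingRate point or \code{c(min, max)} for psi.
#' @rdname BDParams-class
#' @examples
#' BDParams(c(0.041, 0.081), c(0.0011, 0.37), c(0.0066, 0.01806))
#' @export
BDParams <- function(netDiversification, turnover, samplingRate) {
  new("BDParams",
      netDiversification = .range2(netDiversification, "netDiversification"),
      turnover = .range2(turnover, "turnover"),
      samplingRate = .range2(samplingRate, "samplingRate"))
}

#' A fossil first-occurrence record
#'
#' A fossil with its stratigraphic age interval \code{[ageMin, ageMax]} (Ma)
#' and, when it is one of two candidate first records of a clade, the
#' probability that it is the true first record.
#'
#' @slot name character, free-text fossil name.
#' @slot ageMin numeric, younger stratigraphic bound (Ma).
#' @slot ageMax numeric, older stratigraphic bound (Ma).
#' @slot weight numeric in [0, 1].
#' @export
setClass("FossilRecord", representation(
  name = "character", ageMin = "numeric", ageMax = "numeric",
  weight = "numeric"
))

setValidity("FossilRecord", function(object) {
  if (object@ageMin < 0) return("ageMin must be >= 0")
  if (object@ageMin > object@ageMax) return("ageMin must be <= ageMax")
  if (object@weight < 0 || object@weight > 1)
    return("weight must lie in [0, 1]")
  TRUE
})

#' @param name fossil name.
#' @param ageMin,ageMax stratigraphic age bounds in Ma (ageMin <= ageMax).
#' @param weight probability that this fossil is the clade's first record.
#' @rdname FossilRecord-class
#' @export
FossilRecord <- function(name, ageMin, ageMax = ageMin, weight = 1) {
  new("FossilRecord", name = as.character(name), ageMin = as.numeric(ageMin),
      ageMax = as.numeric(ageMax), weight = as.numeric(weight))
}

#' A clade calibration constraint
#'
#' Binds one or two candidate first-record fossils to the crown node defined
#' by a set of tip names. With two fossils the weights must sum to 1 and the
#' fossil with the smaller age bounds is treated as the younger candidate.
#'
#' @slot cladeLabel character label.
#' @slot tipSet character vector of taxon names spanning the calibrated node.
#' @slot fossils list of one or two \code{FossilRecord} objects.
#' @export
setClass("CladeConstraint", representation(
  cladeLabel = "character", tipSet = "character", fossils = "list"
))

setValidity("CladeConstraint", function(object) {
  nf <- length(object@fossils)
  if (nf < 1L || nf > 2L)
    return("a clade takes one or two candidate first-record fossils")
  if (!all(vapply(object@fossils, is, logical(1L), "FossilRecord")))
    return("fossils must be FossilRecord objects")
  if (length(object@tipSet) < 1L) return("tipSet must be non-empty")
  if (nf == 2L) {
    w <- sum(vapply(object@fossils, slot, numeric(1L), "weight"))
    if (abs(w - 1) > 1e-9)
      return(sprintf("fossil weights must sum to 1 (got %.12g)", w))
  }
  TRUE
})

#' @param cladeLabel clade label.
#' @param tipSet taxon names whose most recent common ancestor is calibrated.
#' @param fossils a \code{FossilRecord} or list of one or two of them.
#' @rdname CladeConstraint-class
#' @export
CladeConstraint <- function(cladeLabel, tipSet, fossils) {
  if (is(fossils, "FossilRecord")) fossils <- list(fossils)
  if (length(fossils) == 1L && isTRUE(all.equal(fossils[[1L]]@weight, 1)) == FALSE)
    fossils[[1L]]@weight <- 1
  new("CladeConstraint", cladeLabel = as.character(cladeLabel),
      tipSet = as.character(tipSet), fossils = fossils)
}

#' A tabulated clade-age calibration density
#'
#' The prior density f(t) for the age t (Ma) of a calibrated clade, tabulated
#' on an ascending age grid starting at the youngest possible fossil age.
#' Evaluation between grid points is by linear interpolation; the density is 0
#' outside the tabulated support. For two-fossil mixtures the per-fossil
#' component densities and their weights are retained in \code{components}.
#'
#' @slot ageGrid ascending ages (Ma).
#' @slot densityValues f(t) at each grid age; integrates to 1.
#' @slot cdfValues cumulative integral of the density at each grid age.
#' @slot components list; for mixtures: \code{younger}, \code{older}
#'   (two-column age/density matrices) and \code{weights}.
#' @export
setClass("CalibrationDensity", representation(
  ageGrid = "numeric", densityValues = "numeric", cdfValues = "numeric",
  components = "list"
))

setValidity("CalibrationDensity", function(object) {
  g <- object@ageGrid
  f <- object@densityValues
  if (length(g) < 2L) return("age grid needs at least two points")
  if (is.unsorted(g, strictly = TRUE)) return("age grid must be ascending")
  if (length(f) != length(g)) return("density and grid lengths differ")
  if (any(f < 0)) return("density values must be >= 0")
  tot <- sum(diff(g) * (f[-1L] + f[-length(f)]) / 2)
  if (abs(tot - 1) > 0.01)
    return(sprintf("density must integrate to 1 +- 0.01 (got %.4f)", tot))
  TRUE
})

.newCalibrationDensity <- function(grid, dens, components = list()) {
  tot <- sum(diff(grid) * (dens[-1L] + dens[-length(dens)]) / 2)
  dens <- dens / tot
  # rescale stored mixture components by the same factor so the pointwise
  # identity f = p_y * f_y + p_o * f_o holds exactly on the grid
  if (length(components)) {
    for (nm in c("younger", "older"))
      if (!is.null(components[[nm]]))
        components[[nm]][, "density"] <- components[[nm]][, "density"] / tot
  }
  cdf <- c(0, cumsum(diff(grid) * (dens[-1L] + dens[-length(dens)]) / 2))
  cdf <- pmin(cdf / cdf[length(cdf)], 1)
  new("CalibrationDensity", ageGrid = grid, densityValues = dens,
      cdfValues = cdf, components = components)
}

#' A rooted, ultrametric time tree
#'
#' Wraps an \code{ape} \code{phylo} topology together with node ages in Ma.
#' Tips sit at age 0 and every parent is strictly older than its children;
#' branch lengths are parent age minus child age (Myr).
#'
#' @slot phylo a rooted binary \code{ape::phylo} object.
#' @slot nodeAges numeric vector of ages (Ma) indexed by ape node number
#'   (tips 1..n, then internal nodes).
#' @export
setClass("TimeTree", representation(phylo = "ANY", nodeAges = "numeric"))

setValidity("TimeTree", function(object) {
  phy <- object@phylo
  if (!inherits(phy, "phylo")) return("phylo slot must be an ape phylo")
  n <- length(phy$tip.label)
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  if (phy$Nnode != n - 1L) return("tree must be strictly binary")
  ages <- object@nodeAges
  if (length(ages) != n + phy$Nnode)
    return("nodeAges must have one entry per tip and internal node")
  if (any(abs(ages[seq_len(n)]) > 1e-6)) return("tips must sit at age 0")
  if (anyDuplicated(phy$tip.label)) return("tip names must be unique")
  bad <- ages[phy$edge[, 1L]] <= ages[phy$edge[, 2L]]
  if (any(bad)) return("every parent must be strictly older than its child")
  TRUE
})

#' MCMC sampler settings
#'
#' @slot iterations total Metropolis-Hastings iterations.
#' @slot thinning keep every thinning-th state.
#' @slot burninFraction fraction of retained samples summaries discard.
#' @slot operatorWeights named numeric: relative weights of the
#'   \code{nodeSlide}, \code{subtreeScale}, \code{rootScale} and
#'   \code{uniformRedraw} proposal operators.
#' @slot slideWindow node-slide half-window for the root (Myr).
#' @slot scaleFactor log-uniform scale bound (> 1) for scaling operators.
#' @slot seed integer RNG seed.
#' @export
setClass("MCMCConfig", representation(
  iterations = "numeric", thinning = "numeric", burninFraction = "numeric",
  operatorWeights = "numeric", slideWindow = "numeric",
  scaleFactor = "numeric", seed = "numeric"
))

setValidity("MCMCConfig", function(object) {
  if (object@iterations < object@thinning || object@thinning < 1)
    return("need iterations >= thinning >= 1")
  if (object@burninFraction < 0 || object@burninFraction >= 1)
    return("burninFraction must lie in [0, 1)")
  if (object@scaleFactor <= 1) return("scaleFactor must exceed 1")
  ops <- c("nodeSlide", "subtreeScale", "rootScale", "uniformRedraw")
  if (!all(ops %in% names(object@operatorWeights)))
    return("operatorWeights must name all four operators")
  if (any(object@operatorWeights < 0) || sum(object@operatorWeights) <= 0)
    return("operator weights must be >= 0 and not all zero")
  TRUE
})

#' @param iterations,thinning,burninFraction,seed see slots.
#' @param operatorWeights named weights for the four proposal operators.
#' @param slideWindow root slide half-window (Myr).
#' @param scaleFactor scale-operator bound.
#' @rdname MCMCConfig-class
#' @export
MCMCConfig <- function(iterations = 1e5, thinning = 10,
                       burninFraction = 0.1,
                       operatorWeights = c(nodeSlide = 3, subtreeScale = 1,
                                           rootScale = 1, uniformRedraw = 1),
                       slideWindow = 10, scaleFactor = 1.3, seed = 1L) {
  new("MCMCConfig", iterations = iterations, thinning = thinning,
      burninFraction = burninFraction, operatorWeights = operatorWeights,
      slideWindow = slideWindow, scaleFactor = scaleFactor, seed = seed)
}

#' An MCMC trace of node ages and model parameters
#'
#' @slot samples data.frame with columns iteration, logPosterior, the root
#'   age, one age column per internal node, and (posterior runs) clockRate.
#' @slot thinning thinning interval used.
#' @slot burninFraction fraction summaries discard.
#' @slot seed RNG seed the run used.
#' @slot meta list: calibrated-node map, operator acceptance rates, rates used.
#' @export
setClass("MCMCTrace", representation(
  samples = "data.frame", thinning = "numeric", burninFraction = "numeric",
  seed = "numeric", meta = "list"
))

setValidity("MCMCTrace", function(object) {
  s <- object@samples
  if (!all(c("iteration", "logPosterior") %in% names(s)))
    return("samples must carry iteration and logPosterior columns")
  if (nrow(s) && any(!is.finite(s$logPosterior)))
    return("log posterior must be finite at every retained sample")
  TRUE
})

#' A nucleotide substitution model (GTR + discrete gamma)
#'
#' Exchangeabilities are in the order AC, AG, AT, CG, CT, GT. The rate matrix
#' is rescaled so the mean substitution rate at equilibrium is 1: branch
#' lengths in expected substitutions are clock rate times duration in Myr.
#'
#' @slot rates numeric(6) GTR exchangeabilities, all > 0.
#' @slot baseFreqs numeric(4) equilibrium frequencies (A, C, G, T), sum 1.
#' @slot gammaShape shape of the gamma rate-variation distribution.
#' @slot nCategories number of discrete gamma categories (1 = no variation).
#' @export
setClass("SubstModel", representation(
  rates = "numeric", baseFreqs = "numeric", gammaShape = "numeric",
  nCategories = "numeric"
))

setValidity("SubstModel", function(object) {
  if (length(object@rates) != 6L || any(object@rates <= 0))
    return("need 6 positive exchangeabilities")
  if (length(object@baseFreqs) != 4L || any(object@baseFreqs <= 0) ||
      abs(sum(object@baseFreqs) - 1) > 1e-8)
    return("base frequencies must be 4 positive values summing to 1")
  if (object@gammaShape <= 0) return("gamma shape must be > 0")
  if (object@nCategories < 1) return("need at least one rate category")
  TRUE
})

#' @param rates GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param baseFreqs equilibrium base frequencies (A, C, G, T).
#' @param gammaShape gamma shape for among-site rate variation.
#' @param nCategories discrete gamma categories.
#' @rdname SubstModel-class
#' @examples
#' SubstModel()  # Jukes-Cantor-like defaults
#' @export
SubstModel <- function(rates = rep(1, 6), baseFreqs = rep(0.25, 4),
                       gammaShape = 1, nCategories = 4L) {
  new("SubstModel", rates = rates, baseFreqs = baseFreqs,
      gammaShape = gammaShape, nCategories = as.numeric(nCategories))
}

#' A root-age prior specification
#'
#' The birth-death node-age prior conditions on the root age; the prior on
#' the root age itself is a configuration choice. \code{"flat"} is an
#' improper constant density (useful when the posterior should reproduce a
#' calibration density exactly), \code{"uniform"} has bounds, \code{"normal"}
#' a mean and sd in Ma.
#'
#' @slot type one of "flat", "uniform", "normal".
#' @slot pars numeric parameters (uniform: min, max; normal: mean, sd).
#' @export
setClass("RootPrior", representation(type = "character", pars = "numeric"))

#' @param type "flat", "uniform" or "normal".
#' @param ... for "uniform": min, max; for "normal": mean, sd.
#' @rdname RootPrior-class
#' @examples
#' rootPrior("normal", mean = 300, sd = 0.1)
#' @export
rootPrior <- function(type = c("flat", "uniform", "normal"), ...) {
  type <- match.arg(type)
  pars <- unlist(list(...))
  if (type == "uniform") {
    if (length(pars) != 2L || pars[1L] >= pars[2L])
      stop("uniform root prior needs min < max")
  } else if (type == "normal") {
    if (length(pars) != 2L || pars[2L] <= 0)
      stop("normal root prior needs a mean and a positive sd")
  } else pars <- numeric(0)
  new("RootPrior", type = type, pars = as.numeric(pars))
}

.rootLogDensity <- function(prior, age) {
  switch(prior@type,
    flat = 0,
    uniform = ifelse(age >= prior@pars[1L] & age <= prior@pars[2L],
                     -log(prior@pars[2L] - prior@pars[1L]), -Inf),
    normal = stats::dnorm(age, prior@pars[1L], prior@pars[2L], log = TRUE))
}
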