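#' Clade-age calibration densities from fossil first occurrences
#'
#' A calibration density f(t) is the prior probability density that a clade
#' is of age t (Ma), given the age of its first fossil record and the rates
#' of diversification and fossil sampling. It is the conditional expectation
#'
#'   f(t) = E[ psi * N * exp(-psi * S) | N >= 1 ],
#'
#' where N is the number of lineages of the clade alive at the moment of
#' fossilisation, S is the total lineage duration accumulated between clade
#' origin and fossilisation, and the expectation runs over birth-death
#' histories surviving to the fossilisation time. The expectation is
#' estimated by Monte Carlo: each replicate draws the fossil age uniformly
#' from its stratigraphic interval and each rate uniformly from its range,
#' simulates one lineage history, and contributes to every grid age at once.
#'
#' @param bd a \code{\link{BDParams}} object (points or ranges).
#' @param fossil a \code{\link{FossilRecord}} giving the first record.
#' @param gridSpec optional list: \code{n} grid points (default 1000),
#'   \code{upper} explicit upper age (Ma; default adaptive: where the
#'   unnormalised density falls below \code{tailFraction} of its maximum,
#'   capped at 10 times the 0.999 quantile), \code{tailFraction}
#'   (default 1e-6).
#' @param nReps Monte-Carlo replicates (default 1e5).
#' @param seed RNG seed; identical seed and inputs give identical densities.
#' @return a \code{\linkS4class{CalibrationDensity}}.
#' @examples
#' bd <- BDParams(1e-9, 0, 0.05)
#' d <- singleCalibrationDensity(bd, FossilRecord("pt", 100), nReps = 5e3,
#'                               seed = 1)
#' evaluateDensity(d, 110)  # close to 0.05 * exp(-0.05 * 10)
#' @seealso \code{\link{mixtureCalibrationDensity}} for ambiguous first
#'   records.
#' @export
singleCalibrationDensity <- function(bd, fossil, gridSpec = NULL,
                                     nReps = 1e5, seed = NULL) {
  stopifnot(is(bd, "BDParams"), is(fossil, "FossilRecord"), nReps >= 1)
  validObject(bd); validObject(fossil)
  if (!is.null(seed)) set.seed(seed)
  tab <- .componentTable(bd, fossil@ageMin, fossil@ageMax, gridSpec, nReps)
  .newCalibrationDensity(tab$grid, tab$dens)
}

#' Weighted two-fossil mixture calibration density
#'
#' When two fossils are candidate first records of the same clade, the
#' calibration density is the weighted sum of the two per-fossil densities:
#' below the older fossil's age only the younger component contributes
#' (p_younger * f_younger); at and above it, both do
#' (p_younger * f_younger + p_older * f_older). Weights are the probabilities
#' that each fossil is the true first record and must sum to 1.
#'
#' @param younger,older \code{\link{FossilRecord}}s; the record with the
#'   smaller age-interval midpoint is treated as the younger candidate (a
#'   warning is emitted if the intervals overlap).
#' @inheritParams singleCalibrationDensity
#' @return a \code{\linkS4class{CalibrationDensity}} whose
#'   \code{components} hold the per-fossil densities and weights.
#' @examples
#' bd <- BDParams(c(0.041, 0.081), c(0.0011, 0.37), c(0.0066, 0.01806))
#' cret <- FossilRecord("Cretatriacanthus", 83.0, 89.8, weight = 2/3)
#' plec <- FossilRecord("Plectocretacicus", 98.0, 100.3, weight = 1/3)
#' d <- mixtureCalibrationDensity(cret, plec, bd, nReps = 5e3, seed = 1)
#' @export
mixtureCalibrationDensity <- function(younger, older, bd, gridSpec = NULL,
                                      nReps = 1e5, seed = NULL) {
  stopifnot(is(younger, "FossilRecord"), is(older, "FossilRecord"),
            is(bd, "BDParams"))
  validObject(younger); validObject(older); validObject(bd)
  w <- younger@weight + older@weight
  if (abs(w - 1) > 1e-9)
    stop(sprintf("invalid weights: must sum to 1 (got %.12g)", w))
  midY <- (younger@ageMin + younger@ageMax) / 2
  midO <- (older@ageMin + older@ageMax) / 2
  if (midY > midO) {  # order candidates by interval midpoint
    tmp <- younger; younger <- older; older <- tmp
  }
  if (older@ageMin < younger@ageMax)
    warning("fossil age intervals overlap; candidates ordered by midpoint")
  if (!is.null(seed)) set.seed(seed)

  pY <- younger@weight; pO <- older@weight
  if (pO == 0)  # degenerate mixture: exactly the single-fossil density
    return(.mixtureFromTables(
      .componentTable(bd, younger@ageMin, younger@ageMax, gridSpec, nReps),
      NULL, pY, pO))
  if (pY == 0)
    return(.mixtureFromTables(
      NULL,
      .componentTable(bd, older@ageMin, older@ageMax, gridSpec, nReps),
      pY, pO))

  tabO <- .componentTable(bd, older@ageMin, older@ageMax, gridSpec, nReps)
  # shared grid spans from the younger fossil's minimum age to the older
  # component's adaptive upper bound
  gs <- .gridSpecDefaults(gridSpec)
  gs$upper <- max(tabO$grid)
  tabY <- .componentTable(bd, younger@ageMin, younger@ageMax, gs, nReps)
  tabO <- list(grid = tabY$grid,
               dens = .interpDensity(tabO$grid, tabO$dens, tabY$grid))
  .mixtureFromTables(tabY, tabO, pY, pO)
}

.mixtureFromTables <- function(tabY, tabO, pY, pO) {
  if (is.null(tabO)) {
    comps <- list(younger = cbind(age = tabY$grid, density = tabY$dens),
                  older = NULL, weights = c(younger = pY, older = pO))
    return(.newCalibrationDensity(tabY$grid, tabY$dens, comps))
  }
  if (is.null(tabY)) {
    comps <- list(younger = NULL,
                  older = cbind(age = tabO$grid, density = tabO$dens),
                  weights = c(younger = pY, older = pO))
    return(.newCalibrationDensity(tabO$grid, tabO$dens, comps))
  }
  dens <- pY * tabY$dens + pO * tabO$dens
  comps <- list(younger = cbind(age = tabY$grid, density = tabY$dens),
                older = cbind(age = tabY$grid, density = tabO$dens),
                weights = c(younger = pY, older = pO))
  .newCalibrationDensity(tabY$grid, dens, comps)
}

.gridSpecDefaults <- function(gridSpec) {
  gs <- list(n = 1000L, upper = NULL, tailFraction = 1e-6)
  if (!is.null(gridSpec)) {
    if (!is.list(gridSpec)) stop("invalid grid: gridSpec must be a list")
    gs[names(gridSpec)] <- gridSpec
  }
  if (!is.null(gs$grid) && length(gs$grid) < 2L)
    stop("invalid grid: need at least two grid ages")
  gs
}

# normalised Monte-Carlo density for one fossil, adaptive grid
.componentTable <- function(bd, ageMin, ageMax, gridSpec, nReps) {
  gs <- .gridSpecDefaults(gridSpec)
  psi <- bd@samplingRate; d <- bd@netDiversification; eps <- bd@turnover
  if (!is.null(gs$grid)) {
    grid <- sort(as.numeric(gs$grid))
    if (max(grid) < ageMin)
      stop("invalid grid: entirely below the fossil's minimum age")
  } else {
    upper <- gs$upper
    if (is.null(upper)) {
      # pilot pass: generous exponential-tail bound, then trim where the
      # unnormalised density falls below tailFraction of its maximum
      u0 <- ageMax + pmin(14 / psi[1L], 5000)
      pg <- seq(ageMin, u0, length.out = 256L)
      pd <- .kernelDensity(pg, ageMin, ageMax, psi, d, eps,
                           min(nReps, 4000L))
      keep <- which(pd >= gs$tailFraction * max(pd))
      upper <- pg[min(length(pg), max(keep) + 1L)]
      cdf <- cumsum(pd) / sum(pd)
      q999 <- pg[which(cdf >= 0.999)[1L]]
      upper <- min(upper, 10 * q999)
      upper <- max(upper, ageMax + 1)
    }
    grid <- seq(ageMin, upper, length.out = as.integer(gs$n))
  }
  dens <- .kernelDensity(grid, ageMin, ageMax, psi, d, eps, nReps)
  if (all(dens == 0)) stop("density is zero everywhere on the grid")
  tot <- sum(diff(grid) * (dens[-1L] + dens[-length(dens)]) / 2)
  list(grid = grid, dens = dens / tot)
}

# unnormalised density on a grid of absolute ages
.kernelDensity <- function(grid, tfMin, tfMax, psi, d, eps, nReps) {
  k <- bd_density_kernel_cpp(grid, tfMin, tfMax, psi[1L], psi[2L], d[1L],
                             d[2L], eps[1L], eps[2L], as.integer(nReps))
  f <- ifelse(k$alive > 0, k$g_sum / k$alive, 0)
  f * (k$valid / nReps)
}

.interpDensity <- function(grid, dens, at) {
  out <- stats::approx(grid, dens, xout = at, yleft = 0, yright = 0)$y
  out[is.na(out)] <- 0
  out
}
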