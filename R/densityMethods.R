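#' Evaluate, integrate, invert and sample a calibration density
#'
#' \code{evaluateDensity} interpolates f(t) linearly between grid points and
#' returns 0 outside the tabulated support. \code{logDensity} is its
#' logarithm (-Inf outside the support). \code{densityCDF} is the running
#' trapezoid integral, monotone from 0 to 1; \code{densityQuantile} is its
#' generalised inverse. \code{sampleAges} draws ages by inverse-CDF sampling.
#'
#' @param object a \code{\linkS4class{CalibrationDensity}}.
#' @param t age(s) in Ma, >= 0.
#' @param q probability(ies) in [0, 1].
#' @param n number of draws.
#' @param seed RNG seed.
#' @return numeric vector of densities, log densities, probabilities,
#'   quantiles (Ma) or sampled ages (Ma).
#' @examples
#' bd <- BDParams(1e-9, 0, 0.1)
#' d <- singleCalibrationDensity(bd, FossilRecord("f", 50), nReps = 2e3,
#'                               seed = 1)
#' densityCDF(d, densityQuantile(d, 0.5))
#' @name evaluateDensity
NULL

#' @rdname evaluateDensity
#' @export
setMethod("evaluateDensity", "CalibrationDensity", function(object, t) {
  if (any(t < 0)) stop("domain error: ages must be >= 0")
  out <- stats::approx(object@ageGrid, object@densityValues, xout = t,
                       yleft = 0, yright = 0)$y
  out[is.na(out)] <- 0
  out
})

#' @rdname evaluateDensity
#' @export
setMethod("logDensity", "CalibrationDensity", function(object, t) {
  log(evaluateDensity(object, t))
})

#' @rdname evaluateDensity
#' @export
setMethod("densityCDF", "CalibrationDensity", function(object, t) {
  if (any(t < 0)) stop("domain error: ages must be >= 0")
  out <- stats::approx(object@ageGrid, object@cdfValues, xout = t,
                       yleft = 0, yright = 1)$y
  out[is.na(out)] <- 0
  out
})

#' @rdname evaluateDensity
#' @export
setMethod("densityQuantile", "CalibrationDensity", function(object, q) {
  if (any(q < 0 | q > 1)) stop("domain error: probabilities must be in [0, 1]")
  cdf <- object@cdfValues
  grid <- object@ageGrid
  # generalised inverse; collapse flat CDF stretches to their left edge
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], grid[keep], xout = q, ties = "ordered",
                rule = 2)$y
})

#' @rdname evaluateDensity
#' @export
setMethod("sampleAges", "CalibrationDensity", function(object, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  densityQuantile(object, stats::runif(n))
})

#' Export a calibration density as a two-column table
#'
#' @param object a \code{CalibrationDensity}.
#' @return data.frame with columns \code{age} (Ma) and \code{density}.
#' @export
densityTable <- function(object) {
  stopifnot(is(object, "CalibrationDensity"))
  data.frame(age = object@ageGrid, density = object@densityValues)
}
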