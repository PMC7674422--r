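#' @rdname evaluateDensity
#' @export
setGeneric("evaluateDensity", function(object, t) standardGeneric("evaluateDensity"))

#' @rdname evaluateDensity
#' @export
setGeneric("logDensity", function(object, t) standardGeneric("logDensity"))

#' @rdname evaluateDensity
#' @export
setGeneric("densityCDF", function(object, t) standardGeneric("densityCDF"))

#' @rdname evaluateDensity
#' @export
setGeneric("densityQuantile", function(object, q) standardGeneric("densityQuantile"))

#' @rdname evaluateDensity
#' @export
setGeneric("sampleAges", function(object, n, seed = NULL) standardGeneric("sampleAges"))

#' @rdname accessors
#' @export
setGeneric("ageGrid", function(object) standardGeneric("ageGrid"))

#' @rdname accessors
#' @export
setGeneric("densityValues", function(object) standardGeneric("densityValues"))

#' @rdname accessors
#' @export
setGeneric("densityComponents", function(object) standardGeneric("densityComponents"))

#' @rdname accessors
#' @export
setGeneric("nodeAges", function(object) standardGeneric("nodeAges"))

#' @rdname accessors
#' @export
setGeneric("rootAge", function(object) standardGeneric("rootAge"))

#' @rdname accessors
#' @export
setGeneric("tipNames", function(object) standardGeneric("tipNames"))

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(object, dropBurnin = FALSE) standardGeneric("traceSamples"))

#' Accessors for fossilcal objects
#'
#' @param object a fossilcal S4 object.
#' @param dropBurnin drop the burn-in portion of a trace.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("ageGrid", "CalibrationDensity", function(object) object@ageGrid)

#' @rdname accessors
#' @export
setMethod("densityValues", "CalibrationDensity", function(object) object@densityValues)

#' @rdname accessors
#' @export
setMethod("densityComponents", "CalibrationDensity", function(object) object@components)

#' @rdname accessors
#' @export
setMethod("nodeAges", "TimeTree", function(object) object@nodeAges)

#' @rdname accessors
#' @export
setMethod("rootAge", "TimeTree", function(object) {
  n <- length(object@phylo$tip.label)
  object@nodeAges[n + 1L]
})

#' @rdname accessors
#' @export
setMethod("tipNames", "TimeTree", function(object) object@phylo$tip.label)

#' @rdname accessors
#' @export
setMethod("traceSamples", "MCMCTrace", function(object, dropBurnin = FALSE) {
  s <- object@samples
  if (dropBurnin && nrow(s)) {
    drop <- floor(object@burninFraction * nrow(s))
    if (drop > 0L) s <- s[-seq_len(drop), , drop = FALSE]
  }
  s
})

setMethod("show", "BDParams", function(object) {
  fmt <- function(x) if (x[1L] == x[2L]) sprintf("%g", x[1L]) else
    sprintf("[%g, %g]", x[1L], x[2L])
  cat("BDParams (per lineage per Myr)\n",
      "  net diversification d: ", fmt(object@netDiversification), "\n",
      "  turnover eps:          ", fmt(object@turnover), "\n",
      "  fossil sampling psi:   ", fmt(object@samplingRate), "\n", sep = "")
})

setMethod("show", "FossilRecord", function(object) {
  cat(sprintf("FossilRecord '%s': %g-%g Ma (weight %.3g)\n", object@name,
              object@ageMax, object@ageMin, object@weight))
})

setMethod("show", "CladeConstraint", function(object) {
  cat(sprintf("CladeConstraint '%s' on %d tips, %d fossil(s)\n",
              object@cladeLabel, length(object@tipSet),
              length(object@fossils)))
  for (f in object@fossils) show(f)
})

setMethod("show", "CalibrationDensity", function(object) {
  g <- object@ageGrid
  cat(sprintf(
    "CalibrationDensity on [%.2f, %.2f] Ma (%d grid points)%s\n",
    g[1L], g[length(g)], length(g),
    if (length(object@components)) ", two-fossil mixture" else ""))
  q <- densityQuantile(object, c(0.025, 0.5, 0.975))
  cat(sprintf("  median %.2f Ma, 95%% equal-tail [%.2f, %.2f] Ma\n",
              q[2L], q[1L], q[3L]))
})

setMethod("show", "TimeTree", function(object) {
  cat(sprintf("TimeTree: %d tips, root age %.3f Ma\n",
              length(object@phylo$tip.label), rootAge(object)))
})

setMethod("show", "MCMCTrace", function(object) {
  cat(sprintf("MCMCTrace: %d retained samples (thinning %d, seed %d)\n",
              nrow(object@samples), as.integer(object@thinning),
              as.integer(object@seed)))
})
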