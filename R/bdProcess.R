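#' Convert net diversification and turnover to speciation and extinction rates
#'
#' The diversification process is parameterised by the net diversification
#' rate d = lambda - mu and the turnover eps = mu / lambda. This inverts the
#' reparameterisation: lambda = d / (1 - eps), mu = eps * d / (1 - eps).
#'
#' @param d net diversification rate (per lineage per Myr), >= 0.
#' @param eps turnover ratio mu/lambda in [0, 1).
#' @return list with elements \code{lambda} and \code{mu}.
#' @examples
#' deriveRates(0.05, 0.5)  # lambda = 0.10, mu = 0.05
#' @export
deriveRates <- function(d, eps) {
  if (!is.numeric(d) || d < 0) stop("invalid rate: d must be >= 0")
  if (!is.numeric(eps) || eps < 0 || eps >= 1)
    stop("invalid turnover: eps must lie in [0, 1)")
  list(lambda = d / (1 - eps), mu = eps * d / (1 - eps))
}

#' Simulate birth-death lineage histories conditioned on survival
#'
#' Simulates the time-homogeneous birth-death process from a single lineage
#' with exact (Gillespie) event times, rejecting histories in which the clade
#' is extinct at elapsed time \code{t}. Each accepted history reports N, the
#' number of lineages alive at \code{t}, and S(t), the total lineage duration
#' accumulated on the clade in [0, t] (extinct side branches contribute the
#' time they lived, since fossils can be sampled from them).
#'
#' @param lambda speciation rate (per lineage per Myr).
#' @param mu extinction rate (per lineage per Myr).
#' @param t elapsed time (Myr).
#' @param nReps number of accepted histories to return.
#' @param seed RNG seed (each call is independently seeded).
#' @param maxAttempts rejection cap per accepted sample.
#' @return data.frame with columns \code{N} and \code{S}; attribute
#'   \code{acceptance} holds the empirical acceptance rate.
#' @examples
#' h <- simulateConditionedBD(0.05, 0, t = 20, nReps = 100, seed = 1)
#' mean(h$N)  # close to exp(0.05 * 20)
#' @export
simulateConditionedBD <- function(lambda, mu, t, nReps, seed = NULL,
                                  maxAttempts = 1e7) {
  stopifnot(lambda >= 0, mu >= 0, t >= 0, nReps >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- bd_simulate_cpp(lambda, mu, t, as.integer(nReps), maxAttempts)
  out <- data.frame(N = res$N, S = res$S)
  attr(out, "acceptance") <- nReps / res$attempts
  out
}

#' Analytic survival probability of the birth-death process
#'
#' Probability that a process started from one lineage has at least one
#' surviving lineage after elapsed time t.
#'
#' @param lambda,mu speciation and extinction rates.
#' @param t elapsed time (Myr).
#' @return survival probability.
#' @export
bdSurvivalProbability <- function(lambda, mu, t) {
  if (mu == 0) return(rep_len(1, length(t)))
  if (lambda == mu) return(1 / (1 + lambda * t))
  r <- lambda - mu
  r / (lambda - mu * exp(-r * t))
}

# log p1(t): probability density kernel that a lineage alive t Myr ago has
# exactly one sampled descendant today (complete sampling), up to constants.
.logP1 <- function(t, lambda, mu) {
  r <- lambda - mu
  2 * log(r) - r * t - 2 * log(lambda - mu * exp(-r * t))
}

# integral of p1 over [0, T]
.intP1 <- function(Tmax, lambda, mu) {
  r <- lambda - mu
  if (mu == 0) return((1 - exp(-lambda * Tmax)) / lambda)
  (r / mu) * (1 / (lambda - mu) - 1 / (lambda - mu * exp(-r * Tmax)))
}

#' Birth-death log prior density over node ages on a fixed topology
#'
#' Joint log density of the internal node ages of a rooted binary ultrametric
#' tree under the reconstructed birth-death process conditioned on the root
#' age, multiplied by a separate root-age prior. Conditioned on the root age
#' T, the non-root internal ages are independently distributed with density
#' proportional to p1(t) on (0, T), restricted to configurations compatible
#' with the topology (every parent older than its children).
#'
#' @param tree a \code{TimeTree}.
#' @param lambda speciation rate, must exceed \code{mu}.
#' @param mu extinction rate, >= 0.
#' @param rootModel a \code{\link{rootPrior}} for the root age.
#' @return finite log density for valid age configurations.
#' @export
bdNodeAgeLogDensity <- function(tree, lambda, mu,
                                rootModel = rootPrior("flat")) {
  stopifnot(is(tree, "TimeTree"), lambda > mu, mu >= 0)
  validObject(tree)
  n <- length(tree@phylo$tip.label)
  ages <- tree@nodeAges
  .bdAgesLogDensityCore(ages[-seq_len(n)], lambda, mu) +
    .rootLogDensity(rootModel, ages[n + 1L])
}

# internalAges: root first, then the other internal nodes (ape order)
.bdAgesLogDensityCore <- function(internalAges, lambda, mu) {
  Troot <- internalAges[1L]
  others <- internalAges[-1L]
  if (Troot <= 0 || any(others <= 0) || any(others >= Troot)) return(-Inf)
  if (!length(others)) return(0)
  sum(.logP1(others, lambda, mu)) -
    length(others) * log(.intP1(Troot, lambda, mu))
}
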