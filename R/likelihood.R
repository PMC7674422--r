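## Strict-clock GTR + discrete-gamma likelihood on a TimeTree.
## Branch lengths in expected substitutions are clockRate * duration (Myr);
## the rate matrix is scaled to mean rate 1 so the clock rate is in expected
## substitutions per site per Myr.

.fc_cache <- new.env(parent = emptyenv())

# eigendecomposition of the scaled GTR rate matrix, cached per model
.gtrEigen <- function(model) {
  key <- paste(c(model@rates, model@baseFreqs), collapse = ",")
  hit <- .fc_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- model@rates; pi <- model@baseFreqs
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- r[1L]; Q[1, 3] <- r[2L]; Q[1, 4] <- r[3L]
  Q[2, 3] <- r[4L]; Q[2, 4] <- r[5L]; Q[3, 4] <- r[6L]
  Q <- Q + t(Q)
  Q <- Q * rep(pi, each = 4)        # q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))       # mean substitution rate at equilibrium
  Q <- Q / scale
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))        # symmetric similarity transform
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  out <- list(U = eg$vectors / sp, Uinv = t(eg$vectors) * rep(sp, each = 4),
              eval = eg$values)
  .fc_cache[[key]] <- out
  out
}

# mean rates of k equal-probability discrete gamma categories
.gammaRates <- function(shape, k) {
  k <- as.integer(k)
  if (k == 1L || !is.finite(shape)) return(rep(1, k))
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape, shape)
  m <- k * diff(stats::pgamma(b, shape + 1, shape))
  m / mean(m)
}

.NUC_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L, `-` = 4L, `?` = 4L)

# alignment (DNAStringSet / named character vector) -> integer matrix
.alignmentMatrix <- function(alignment) {
  if (is(alignment, "DNAStringSet")) {
    seqs <- as.character(alignment)
  } else if (is.character(alignment)) {
    seqs <- alignment
  } else stop("alignment must be a DNAStringSet or named character vector")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("alignment sequences must carry unique taxon names")
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment sequences must all have equal length")
  chars <- toupper(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
  bad <- setdiff(unique(as.vector(chars)), names(.NUC_CODE))
  if (length(bad))
    stop("parse error: unknown characters in alignment: ",
         paste(bad, collapse = ", "))
  m <- matrix(.NUC_CODE[chars], nrow = length(seqs),
              dimnames = list(names(seqs), NULL))
  m
}

# compress an integer site matrix into unique patterns + weights
.sitePatterns <- function(m) {
  key <- apply(m, 2L, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = m[, first, drop = FALSE], weights = as.numeric(tab))
}

#' Strict-clock log likelihood by Felsenstein pruning
#'
#' Computes the log likelihood of a nucleotide alignment on a time tree under
#' a GTR model with discrete-gamma among-site rate variation and a strict
#' molecular clock, using the pruning algorithm with per-site averaging over
#' rate categories. N, - and ? are treated as missing data (a partial vector
#' of ones at the tip).
#'
#' @param alignment a \code{Biostrings::DNAStringSet} or named character
#'   vector of equal-length sequences; names must match the tree tips.
#' @param tree a \code{TimeTree} with ages in Ma.
#' @param clockRate substitutions per site per Myr, > 0.
#' @param model a \code{\link{SubstModel}}.
#' @return the log likelihood (invariant to site order).
#' @examples
#' tr <- simulateTimeTree(4, rootAge = 50, seed = 1)
#' aln <- simulateAlignment(tr, 1e-3, SubstModel(), nSites = 100, seed = 1)
#' felsensteinLogLik(aln, tr, 1e-3, SubstModel())
#' @export
felsensteinLogLik <- function(alignment, tree, clockRate, model) {
  stopifnot(is(tree, "TimeTree"), is(model, "SubstModel"))
  if (clockRate <= 0) stop("clockRate must be > 0")
  m <- .alignmentMatrix(alignment)
  phy <- tree@phylo
  missing <- setdiff(phy$tip.label, rownames(m))
  if (length(missing))
    stop("taxon mapping error: no sequence for ",
         paste(missing, collapse = ", "))
  m <- m[phy$tip.label, , drop = FALSE]
  pat <- .sitePatterns(m)
  po <- ape::reorder.phylo(phy, "postorder")
  blen <- (tree@nodeAges[po$edge[, 1L]] - tree@nodeAges[po$edge[, 2L]]) *
    clockRate
  eg <- .gtrEigen(model)
  rates <- .gammaRates(model@gammaShape, model@nCategories)
  pruning_loglik_cpp(po$edge, blen, pat$patterns, pat$weights,
                     model@baseFreqs, eg$U, eg$Uinv, eg$eval, rates,
                     length(phy$tip.label))
}

#' Simulate a nucleotide alignment on a time tree
#'
#' Sites are independent given their gamma rate category; each site draws a
#' category, the root state from the equilibrium frequencies, and child
#' states down the tree from the per-branch transition matrices.
#'
#' @inheritParams felsensteinLogLik
#' @param nSites number of sites, >= 1.
#' @param seed RNG seed.
#' @return a \code{Biostrings::DNAStringSet} named by the tree tips.
#' @export
simulateAlignment <- function(tree, clockRate, model, nSites, seed = NULL) {
  stopifnot(is(tree, "TimeTree"), is(model, "SubstModel"), nSites >= 1)
  if (clockRate < 0) stop("clockRate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::reorder.phylo(tree@phylo, "cladewise")
  nTip <- length(phy$tip.label)
  nNode <- nTip + phy$Nnode
  eg <- .gtrEigen(model)
  rates <- .gammaRates(model@gammaShape, model@nCategories)
  cat <- sample.int(length(rates), nSites, replace = TRUE)
  pi <- model@baseFreqs

  states <- matrix(0L, nNode, nSites)
  states[nTip + 1L, ] <- sample.int(4L, nSites, replace = TRUE, prob = pi)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    dur <- (tree@nodeAges[par] - tree@nodeAges[ch]) * clockRate
    for (c in seq_along(rates)) {
      idx <- which(cat == c)
      if (!length(idx)) next
      P <- eg$U %*% (exp(eg$eval * dur * rates[c]) * eg$Uinv)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      cum <- t(apply(P, 1L, cumsum))
      u <- stats::runif(length(idx))
      ps <- states[par, idx]
      states[ch, idx] <- 1L + (u > cum[ps, 1L]) + (u > cum[ps, 2L]) +
        (u > cum[ps, 3L])
    }
  }
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(nTip),
                 function(i) paste(bases[states[i, ]], collapse = ""),
                 character(1L))
  names(seqs) <- phy$tip.label
  Biostrings::DNAStringSet(seqs)
}
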