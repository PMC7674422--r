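#' Construct a TimeTree
#'
#' Builds a \code{\linkS4class{TimeTree}} from a rooted, binary, ultrametric
#' \code{ape::phylo} object (ages recovered from edge lengths, tips at 0) or
#' from a topology plus an explicit vector of node ages.
#'
#' @param phylo a rooted binary \code{ape::phylo}.
#' @param nodeAges optional ages (Ma) indexed by ape node number; when NULL
#'   they are derived from the edge lengths, which must be ultrametric.
#' @param tol tolerance (Myr) for the ultrametricity check.
#' @return a \code{TimeTree}.
#' @examples
#' tr <- timeTree(ape::read.tree(text = "((A:10,B:10):5,C:15);"))
#' rootAge(tr)
#' @export
timeTree <- function(phylo, nodeAges = NULL, tol = 1e-6) {
  if (!inherits(phylo, "phylo")) stop("phylo must be an ape phylo object")
  if (!ape::is.rooted(phylo)) stop("invalid tree: must be rooted")
  n <- length(phylo$tip.label)
  if (phylo$Nnode != n - 1L) {
    deg <- tabulate(phylo$edge[, 1L])
    poly <- which(deg > 2L)
    stop("invalid tree: not strictly binary (polytomy at node ",
         paste(poly, collapse = ", "), ")")
  }
  if (is.null(nodeAges)) {
    if (is.null(phylo$edge.length))
      stop("invalid tree: no edge lengths to derive ages from")
    depth <- ape::node.depth.edgelength(phylo)
    ages <- max(depth) - depth
    if (any(abs(ages[seq_len(n)]) > tol))
      stop("invalid tree: not ultrametric (tips do not align at age 0)")
    ages[seq_len(n)] <- 0
    nodeAges <- ages
  }
  phylo$edge.length <- nodeAges[phylo$edge[, 1L]] - nodeAges[phylo$edge[, 2L]]
  if (any(phylo$edge.length <= 0))
    stop("invalid tree: child at least as old as its parent")
  new("TimeTree", phylo = phylo, nodeAges = as.numeric(nodeAges))
}

#' Replace the node ages of a TimeTree
#'
#' @param tree a \code{TimeTree}.
#' @param ages new ages (Ma) for every node (tips must stay 0).
#' @return the updated \code{TimeTree}.
#' @export
setTreeAges <- function(tree, ages) timeTree(tree@phylo, nodeAges = ages)

#' Map a tip set to its most recent common ancestor node
#'
#' The tip set must be monophyletic in the fixed topology: the MRCA's
#' descendant tips must equal the tip set exactly.
#'
#' @param tree a \code{TimeTree}.
#' @param tipSet character vector of tip names.
#' @return internal ape node number of the calibrated node.
#' @export
mrcaNode <- function(tree, tipSet) {
  phy <- tree@phylo
  missing <- setdiff(tipSet, phy$tip.label)
  if (length(missing))
    stop("constraint mapping error: unknown tips ",
         paste(missing, collapse = ", "))
  n <- length(phy$tip.label)
  if (length(tipSet) == n) return(n + 1L)
  if (length(tipSet) == 1L)
    stop("constraint mapping error: a crown node needs at least two tips")
  node <- ape::getMRCA(phy, tipSet)
  desc <- phy$tip.label[.cladeTips(phy, node)]
  if (!setequal(desc, tipSet))
    stop("constraint mapping error: tip set is not monophyletic; MRCA spans ",
         length(desc), " tips")
  node
}

# tip indices descending from an internal node
.cladeTips <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(node)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .cladeTips, phy = phy))
}

# children list and parent map for fast traversal
.treeMaps <- function(phy) {
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  parent <- integer(m)
  children <- vector("list", m)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c <- phy$edge[e, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  list(nTip = n, parent = parent, children = children, root = n + 1L)
}

#' Simulate a random ultrametric time tree
#'
#' Draws a Yule (pure-birth) topology conditioned on the number of tips and
#' rescales it to a chosen root age; used for fixtures and recovery
#' experiments.
#'
#' @param nTips number of tips.
#' @param rootAge root age in Ma.
#' @param seed RNG seed.
#' @return a \code{TimeTree} with tips t1..tn.
#' @export
simulateTimeTree <- function(nTips, rootAge = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rcoal(nTips, tip.label = paste0("t", seq_len(nTips)))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * rootAge / depth
  timeTree(phy)
}
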