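# Independent oracles, deliberately implemented on different code paths than
# the package internals (per-lineage clocks instead of aggregate Gillespie,
# exhaustive state enumeration instead of pruning).

# Birth-death simulation with explicit per-lineage split/death clocks.
# Returns N (lineages alive at t) and S (total lineage duration in [0, t]).
naiveLineageSim <- function(lambda, mu, t) {
  stack <- 0
  N <- 0L
  S <- 0
  while (length(stack)) {
    b <- stack[[1L]]
    stack <- stack[-1L]
    death <- if (mu > 0) b + stats::rexp(1L, mu) else Inf
    endt <- min(death, t)
    if (lambda > 0) {
      tc <- b
      repeat {
        tc <- tc + stats::rexp(1L, lambda)
        if (tc >= endt) break
        stack <- c(stack, tc)
      }
    }
    S <- S + (endt - b)
    if (death > t) N <- N + 1L
  }
  c(N = N, S = S)
}

# conditioned-on-survival replicates via rejection on the naive simulator
naiveConditionedSim <- function(lambda, mu, t, nReps) {
  out <- matrix(0, nReps, 2L, dimnames = list(NULL, c("N", "S")))
  i <- 0L
  while (i < nReps) {
    s <- naiveLineageSim(lambda, mu, t)
    if (s[["N"]] >= 1L) {
      i <- i + 1L
      out[i, ] <- s
    }
  }
  as.data.frame(out)
}

# brute-force estimate of the unnormalised calibration kernel
# E[psi N exp(-psi S) | N >= 1] at a single elapsed time, with its MC se
naiveKernel <- function(lambda, mu, psi, elapsed, nReps) {
  h <- naiveConditionedSim(lambda, mu, elapsed, nReps)
  g <- psi * h$N * exp(-psi * h$S)
  c(mean = mean(g), se = stats::sd(g) / sqrt(nReps))
}

# Forward Yule simulation from a root split at age Tage, conditioned on the
# number of extant tips; returns split ages (Ma) and, for 4 tips, whether the
# shape is balanced (one split on each side of the root).
yuleForwardCond <- function(lambda, Tage, nTips, nAccept) {
  ages <- vector("list", nAccept)
  balanced <- logical(nAccept)
  got <- 0L
  while (got < nAccept) {
    side <- c("L", "R")
    tcur <- 0
    events <- numeric(0)
    evSide <- character(0)
    repeat {
      tcur <- tcur + stats::rexp(1L, length(side) * lambda)
      if (tcur >= Tage) break
      k <- sample.int(length(side), 1L)
      events <- c(events, tcur)
      evSide <- c(evSide, side[k])
      side <- c(side, side[k])
      if (length(side) > nTips) break
    }
    if (length(side) == nTips && tcur >= Tage) {
      got <- got + 1L
      ages[[got]] <- Tage - events     # convert to age before present
      balanced[got] <- length(unique(evSide)) == 2L
    }
  }
  list(ages = ages, balanced = balanced)
}

# exhaustive sum over ancestral state assignments (<= 4 taxa practical)
enumLogLik <- function(alignment, tree, rate, model) {
  m <- fossilcal:::.alignmentMatrix(alignment)
  phy <- tree@phylo
  m <- m[phy$tip.label, , drop = FALSE] + 1L  # 1..4, 5 = missing
  nTip <- length(phy$tip.label)
  eg <- fossilcal:::.gtrEigen(model)
  rates <- fossilcal:::.gammaRates(model@gammaShape, model@nCategories)
  Pm <- function(t) eg$U %*% (exp(eg$eval * t) * eg$Uinv)
  nNode <- nTip + phy$Nnode
  combs <- as.matrix(expand.grid(rep(list(1:4), phy$Nnode)))
  ll <- 0
  for (s in seq_len(ncol(m))) {
    tot <- 0
    for (c in seq_along(rates)) {
      Ps <- lapply(seq_len(nrow(phy$edge)), function(e) {
        dt <- (tree@nodeAges[phy$edge[e, 1L]] -
                 tree@nodeAges[phy$edge[e, 2L]]) * rate * rates[c]
        Pm(dt)
      })
      pr <- 0
      for (r in seq_len(nrow(combs))) {
        asg <- integer(nNode)
        asg[(nTip + 1L):nNode] <- combs[r, ]
        p <- model@baseFreqs[asg[nTip + 1L]]
        for (e in seq_len(nrow(phy$edge))) {
          a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
          if (b <= nTip) {
            st <- m[b, s]
            if (st == 5L) next  # missing tip: sums over states to 1
            p <- p * Ps[[e]][asg[a], st]
          } else {
            p <- p * Ps[[e]][asg[a], asg[b]]
          }
        }
        pr <- pr + p
      }
      tot <- tot + pr / length(rates)
    }
    ll <- ll + log(tot)
  }
  ll
}

# KS distance between samples and a CalibrationDensity
ksAgainstDensity <- function(samples, density) {
  as.numeric(suppressWarnings(stats::ks.test(
    samples, function(q) densityCDF(density, q))$statistic))
}

# teleost rate ranges used throughout the examples
teleostBD <- function() {
  BDParams(c(0.041, 0.081), c(0.0011, 0.37), c(0.0066, 0.01806))
}

twoTipTree <- function(age = 150) {
  timeTree(ape::read.tree(text = sprintf("(A:%g,B:%g);", age, age)))
}
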