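# Independent brute-force oracles used across test files. These never call
# the implementation paths they check.

# Two-sided Fisher p by full enumeration of margin-fixed tables.
bruteFisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  aRange <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(aRange, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Patterson's D by quartet pattern counting on fixed haplotype matrices
# (one 0/1 matrix per group, sites x haplotypes): average ABBA/BABA over
# all cross-group haplotype quartets.
bruteD <- function(hA, hB, hC, hO) {
  abba <- 0; baba <- 0
  for (s in seq_len(nrow(hA))) {
    for (a in hA[s, ]) for (b in hB[s, ]) for (cc in hC[s, ]) for (o in hO[s, ]) {
      if (a == 0 && b == 1 && cc == 1 && o == 0) abba <- abba + 1
      if (a == 1 && b == 0 && cc == 1 && o == 0) baba <- baba + 1
    }
  }
  if (abba + baba == 0) return(NA_real_)
  (abba - baba) / (abba + baba)
}

hapCountsFromMatrix <- function(h) {
  alt <- rowSums(h)
  cbind(ref = ncol(h) - alt, alt = alt)
}

# EHH by direct pair counting: fraction of haplotype pairs identical over
# rows core..x.
bruteEhh <- function(h, core, x) {
  n <- ncol(h)
  span <- core:x
  same <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (all(h[span, i] == h[span, j])) same <- same + 1
  }
  same / choose(n, 2)
}

# Minimum spanning tree weight by exhaustive enumeration over all spanning
# trees (Prufer sequences), n <= 6.
bruteMstWeight <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  pruferToEdges <- function(pr) {
    n <- length(pr) + 2L
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    for (i in seq_along(pr)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, pr[i])
      degree[leaf] <- 0L
      degree[pr[i]] <- degree[pr[i]] - 1L
    }
    edges[n - 1L, ] <- which(degree == 1L)
    edges
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    e <- pruferToEdges(grid[g, ])
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

# Simulated drifted tract in population A: redraw A's counts in the tract
# with extra Balding-Nichols drift about the latent A frequency.
driftTractA <- function(tp, tract, F = 0.3, seed = 1) {
  set.seed(seed)
  i <- tract[1]:tract[2]
  pA <- tp$truth$p_A[i]
  pAd <- rbeta(length(i), pA * (1 - F) / F, (1 - pA) * (1 - F) / F)
  cA <- tp$counts$A
  m <- rowSums(cA)[i]
  alt <- rbinom(length(i), m, pAd)
  cA[i, ] <- cbind(m - alt, alt)
  cA
}
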