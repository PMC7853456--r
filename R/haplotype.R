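## Haplotype-level statistics: LD tagging of a duplication-linked allele,
## identical-haplotype clustering with minimum-spanning-tree networks,
## Garud's H statistics, haplotype diversity, EHH decay, and jackknife
## errors over haplotypes.

#' Rogers-Huff r between two dosage vectors
#'
#' The composite LD correlation for unphased data: Pearson correlation of
#' 0/1/2 genotype dosages over pairwise-complete observations.
#'
#' @param x,y Equal-length dosage vectors; `NA` pairs are deleted.
#' @return r, or `NA` (flagged undefined) when either vector has zero
#'   variance over the complete pairs.
#' @export
rogersHuffR <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Find diploid-region variants tagging a focal (duplication-linked) allele
#'
#' Inside a duplication, phased calls are unreliable, so the focal
#' resistance allele is tracked through nearby diploid-region variants in
#' near-perfect LD with it. A candidate is reported when (i) its
#' Rogers-Huff |r| with the focal site exceeds `rThreshold`, (ii) the
#' per-window haplotype-score and normalised-coverage tracks at its
#' position are both within `tolerance` of 2 (the region is effectively
#' diploid), and (iii) it is present in the phased set.
#'
#' @param gm A [GenotypeMatrix-class] covering the scan region.
#' @param focalSite 1-based position of the focal SNP (excluded from its
#'   own output).
#' @param tracks data.frame with columns `start`, `end` (1-based inclusive
#'   window bounds), `haplotype_score`, `coverage`.
#' @param phasedPositions Positions present in the phased variant set.
#' @param rThreshold LD threshold (default 0.95).
#' @param tolerance Allowed deviation of both tracks from 2 (default 0.25).
#' @return data.frame of tagging variants: `position`, `r`.
#' @export
findTaggingVariants <- function(gm, focalSite, tracks, phasedPositions,
                                rThreshold = 0.95, tolerance = 0.25) {
  stopifnot(is(gm, "GenotypeMatrix"))
  dos <- dosages(gm)
  pos <- positions(gm)
  fi <- match(as.integer(focalSite), pos)
  if (is.na(fi)) stop("focal site not present in genotype matrix")
  r <- vapply(seq_len(nrow(dos)), function(i) rogersHuffR(dos[fi, ], dos[i, ]),
              numeric(1))
  diploid <- vapply(pos, function(p) {
    w <- tracks$start <= p & tracks$end >= p
    any(w & abs(tracks$haplotype_score - 2) <= tolerance &
            abs(tracks$coverage - 2) <= tolerance)
  }, logical(1))
  keep <- !is.na(r) & abs(r) > rThreshold & diploid &
    pos %in% as.integer(phasedPositions) & seq_along(pos) != fi
  data.frame(position = pos[keep], r = r[keep])
}

hammingDist <- function(a, b) sum(a != b)

## Deterministic Kruskal MST over a symmetric distance matrix: edges sorted
## by (weight, i, j) so equal-weight ties always resolve the same way.
kruskalMst <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(data.frame(from = integer(), to = integer(), weight = numeric()))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs], pairs[, 1], pairs[, 2])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  out <- vector("list", n - 1L); k <- 0L
  for (e in ord) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1L
      out[[k]] <- c(i, j, d[i, j])
      if (k == n - 1L) break
    }
  }
  m <- do.call(rbind, out[seq_len(k)])
  data.frame(from = as.integer(m[, 1]), to = as.integer(m[, 2]), weight = m[, 3])
}

#' Cluster identical haplotypes and build a one-step network
#'
#' Collapses identical haplotypes over a window into clusters, computes
#' pairwise Hamming distances between cluster consensus sequences, builds
#' a minimum spanning tree (deterministic tie-break by node index), and
#' removes tree edges with distance > 1, so surviving edges connect
#' clusters separated by exactly one substitution.
#'
#' @param hm [HaplotypeMatrix-class] restricted to the focal window.
#' @param tagAlleles Optional 0/1 vector (one per haplotype) of the allele
#'   carried at the tagging site, recorded per cluster.
#' @param groups Optional labels (e.g. population) per haplotype, tallied
#'   per cluster.
#' @return List of class `haplotypeNetwork` with `nodes` (data.frame:
#'   `node`, `size`, `members` list-column, `tag_freq`, composition
#'   columns) and `edges` (`from`, `to`, `distance`; all distance <= 1),
#'   plus `mst_edges` (the full tree before breaking long edges).
#' @export
buildHaplotypeNetwork <- function(hm, tagAlleles = NULL, groups = NULL) {
  stopifnot(is(hm, "HaplotypeMatrix"))
  h <- haplotypes(hm)
  if (nrow(h) == 0L || ncol(h) == 0L) stop("empty haplotype window")
  key <- apply(h, 2L, paste, collapse = "")
  uk <- unique(key)
  cluster <- match(key, uk)
  sizes <- tabulate(cluster, length(uk))
  nodes <- data.frame(node = seq_along(uk), size = sizes)
  nodes$members <- I(split(hm@haplotypeIds, cluster)[as.character(seq_along(uk))])
  if (!is.null(tagAlleles))
    nodes$tag_freq <- as.numeric(tapply(tagAlleles, cluster, mean))
  if (!is.null(groups)) {
    tab <- table(cluster, groups)
    for (g in colnames(tab)) nodes[[paste0("n_", g)]] <- as.integer(tab[, g])
  }
  rep_h <- h[, match(uk, key), drop = FALSE]
  d <- as.matrix(stats::dist(t(rep_h), method = "manhattan"))
  mst <- kruskalMst(d)
  list2 <- list(
    nodes = nodes,
    edges = mst[mst$weight <= 1, c("from", "to", "weight")] |>
      stats::setNames(c("from", "to", "distance")),
    mst_edges = stats::setNames(mst, c("from", "to", "distance")),
    cluster = cluster
  )
  class(list2) <- "haplotypeNetwork"
  list2
}

#' @export
print.haplotypeNetwork <- function(x, ...) {
  cat(sprintf("Haplotype network: %d clusters (%d haplotypes), %d one-step edges\n",
    nrow(x$nodes), sum(x$nodes$size), nrow(x$edges)))
  invisible(x)
}

haplotypeClusterFreqs <- function(h) {
  key <- apply(h, 2L, paste, collapse = "")
  sort(as.numeric(table(key)) / length(key), decreasing = TRUE)
}

#' Garud's H statistics for one haplotype window
#'
#' With sorted cluster frequencies p1 >= p2 >= ...: H1 = sum(p_i^2),
#' H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2, H2 = H1 - p1^2. H12 boosts the
#' signal of soft sweeps by pooling the two most frequent haplotypes;
#' H2/H1 discriminates hard (low) from soft (high) sweeps.
#'
#' @param h Variant x haplotype 0/1 matrix (>= 2 haplotypes).
#' @return Named list `h1`, `h12`, `h2`, `h2_h1`.
#' @export
garudH <- function(h) {
  if (ncol(h) < 2L) stop("need at least 2 haplotypes")
  p <- haplotypeClusterFreqs(h)
  h1 <- sum(p^2)
  h12 <- if (length(p) >= 2L) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else h1
  h2 <- h1 - p[1]^2
  list(h1 = h1, h12 = h12, h2 = h2, h2_h1 = h2 / h1)
}

#' Haplotype diversity of a window
#'
#' Unbiased gene diversity over whole-window haplotypes:
#' `(1 - sum(p_i^2)) * n/(n-1)`.
#'
#' @inheritParams garudH
#' @return Diversity in [0, 1].
#' @export
haplotypeDiversity <- function(h) {
  n <- ncol(h)
  if (n < 2L) stop("need at least 2 haplotypes")
  p <- haplotypeClusterFreqs(h)
  (1 - sum(p^2)) * n / (n - 1)
}

#' Windowed sweep profile (Garud's H and haplotype diversity)
#'
#' Slides windows of `windowSize` consecutive variants with a step of
#' `windowSize * (1 - overlap)` (adjacent windows share `overlap` of their
#' variants) and computes Garud's H statistics and haplotype diversity in
#' each.
#'
#' @param hm A [HaplotypeMatrix-class]; subset columns first to profile a
#'   haplotype group (e.g. resistance-linked carriers).
#' @param windowSize Variants per window (default 500).
#' @param overlap Fraction of shared variants between adjacent windows
#'   (default 0.2).
#' @return data.frame of windows with `h1`, `h12`, `h2`, `h2_h1`,
#'   `diversity`.
#' @export
sweepProfile <- function(hm, windowSize = 500L, overlap = 0.2) {
  stopifnot(is(hm, "HaplotypeMatrix"))
  step <- max(1L, as.integer(round(windowSize * (1 - overlap))))
  h <- haplotypes(hm)
  starts <- windowStarts(nrow(h), windowSize, step)
  out <- windowFrame(starts, windowSize, positions(hm))
  stats_l <- lapply(starts, function(s) {
    w <- h[(s + 1L):(s + windowSize), , drop = FALSE]
    g <- garudH(w)
    c(h1 = g$h1, h12 = g$h12, h2 = g$h2, h2_h1 = g$h2_h1,
      diversity = haplotypeDiversity(w))
  })
  cbind(out, do.call(rbind, stats_l))
}

#' EHH decay away from a core variant
#'
#' Extended haplotype homozygosity at variant step x is the probability
#' that two randomly drawn haplotypes are identical over every variant
#' from the core through x: `sum_c choose(n_c, 2) / choose(n, 2)` over
#' clusters of haplotypes identical on that span. EHH is 1 at the core and
#' non-increasing outward.
#'
#' @param h Variant x haplotype 0/1 matrix.
#' @param coreIndex 1-based row index of the core variant.
#' @param direction `"down"` (increasing index) or `"up"`.
#' @param maxSteps Cap on the number of steps from the core.
#' @return data.frame with `step` (0 = core), `variant_index`, `ehh`.
#' @export
ehhDecay <- function(h, coreIndex, direction = c("down", "up"),
                     maxSteps = 10000L) {
  direction <- match.arg(direction)
  n <- ncol(h)
  if (n < 2L) stop("need at least 2 haplotypes")
  idx <- if (direction == "down") coreIndex:min(nrow(h), coreIndex + maxSteps)
         else coreIndex:max(1L, coreIndex - maxSteps)
  key <- rep("", n)
  denom <- choose(n, 2)
  ehh <- numeric(length(idx))
  for (s in seq_along(idx)) {
    key <- paste0(key, h[idx[s], ])
    cnt <- table(key)
    ehh[s] <- sum(choose(cnt, 2)) / denom
  }
  data.frame(step = seq_along(idx) - 1L, variant_index = idx, ehh = ehh)
}

#' Flank average of a haplotype statistic with sample-jackknife SE
#'
#' Averages a window statistic over the windows of a flanking region and
#' attaches a leave-one-haplotype-out jackknife standard error: the whole
#' profile is recomputed with each haplotype removed in turn.
#'
#' @param hm [HaplotypeMatrix-class] restricted to the flank.
#' @param statistic Function of a 0/1 matrix returning one number, e.g.
#'   `function(w) garudH(w)$h12`.
#' @param windowSize,overlap As in [sweepProfile()].
#' @return List with `mean`, `se`, `n_haplotypes`.
#' @export
flankAverageWithJackknife <- function(hm, statistic, windowSize = 500L,
                                      overlap = 0.2) {
  stopifnot(is(hm, "HaplotypeMatrix"))
  h <- haplotypes(hm)
  n <- ncol(h)
  if (n < 2L) stop("need at least 2 haplotypes")
  step <- max(1L, as.integer(round(windowSize * (1 - overlap))))
  starts <- windowStarts(nrow(h), windowSize, step)
  if (!length(starts)) { starts <- 0L; windowSize <- nrow(h) }
  avg <- function(mat) {
    mean(vapply(starts, function(s)
      statistic(mat[(s + 1L):(s + windowSize), , drop = FALSE]), numeric(1)))
  }
  est <- avg(h)
  loo <- vapply(seq_len(n), function(i) avg(h[, -i, drop = FALSE]), numeric(1))
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  list(mean = est, se = se, n_haplotypes = n)
}
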