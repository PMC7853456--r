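## Patterson's D from population allele frequencies, with block-jackknife
## significance, and three-population branch lengths used to orient the
## direction of introgression at a duplicated locus.

dFreq <- function(counts) {
  a <- altFreqAndN(counts)
  a$p
}

## Per-site ABBA/BABA expectations from allele frequencies in the
## (((A,B),C),O) topology. The outgroup frequency is used as given (a
## polymorphic outgroup down-weights rather than excludes a site).
abbaBaba <- function(countsA, countsB, countsC, countsO) {
  pA <- dFreq(countsA); pB <- dFreq(countsB)
  pC <- dFreq(countsC); pO <- dFreq(countsO)
  list(
    abba = (1 - pA) * pB * pC * (1 - pO),
    baba = pA * (1 - pB) * pC * (1 - pO)
  )
}

#' Windowed Patterson's D
#'
#' For populations arranged (((A, B), C), O), per-site
#' ABBA = (1-pA) pB pC (1-pO) and BABA = pA (1-pB) pC (1-pO); each
#' window's D is sum(ABBA - BABA) / sum(ABBA + BABA). D > 0 indicates
#' excess allele sharing between B and C, D < 0 between A and C; swapping
#' A and B flips the sign.
#'
#' @param countsA,countsB,countsC,countsO Per-variant (ref, alt) count
#'   matrices on shared variants; O is the outgroup used for polarisation.
#' @param windowSize Variants per window (default 5000).
#' @param stepFraction Step as a fraction of the window (default 0.2, i.e.
#'   windows advance by 20% of their length).
#' @param positions Optional 1-based positions for window coordinates.
#' @return data.frame of windows with `value` (D; `NA` where the
#'   denominator is zero).
#' @export
pattersonD <- function(countsA, countsB, countsC, countsO,
                       windowSize = 5000L, stepFraction = 0.2,
                       positions = NULL) {
  stopifnot(nrow(countsA) == nrow(countsB), nrow(countsA) == nrow(countsC),
            nrow(countsA) == nrow(countsO))
  ab <- abbaBaba(countsA, countsB, countsC, countsO)
  step <- max(1L, as.integer(round(windowSize * stepFraction)))
  starts <- windowStarts(nrow(countsA), windowSize, step)
  out <- windowFrame(starts, windowSize, positions)
  out$value <- vapply(starts, function(s) {
    i <- (s + 1L):(s + windowSize)
    num <- sum(ab$abba[i] - ab$baba[i], na.rm = TRUE)
    den <- sum(ab$abba[i] + ab$baba[i], na.rm = TRUE)
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  out
}

#' Region-average Patterson's D with block-jackknife significance
#'
#' The region D is the ratio-of-sums over all sites in the region (not a
#' mean of window values). A delete-one block jackknife over consecutive
#' blocks of `blockLength` variants yields the SE; Z = D/SE and the
#' p-value is two-sided normal.
#'
#' @inheritParams pattersonD
#' @param region Optional integer c(first, last) 1-based variant index
#'   bounds; defaults to all sites.
#' @param blockLength Variants per jackknife block (default 100).
#' @return List of class `dTest`: `d`, `se`, `z`, `p`, `n_blocks`,
#'   `n_sites`.
#' @export
regionDWithJackknife <- function(countsA, countsB, countsC, countsO,
                                 region = NULL, blockLength = 100L) {
  ab <- abbaBaba(countsA, countsB, countsC, countsO)
  idx <- if (is.null(region)) seq_along(ab$abba)
         else region[1]:region[2]
  num <- (ab$abba - ab$baba)[idx]
  den <- (ab$abba + ab$baba)[idx]
  jk <- blockJackknifeMean(num = num, den = den, blockLength = blockLength)
  z <- if (jk$se == 0) ifelse(jk$mean == 0, 0, sign(jk$mean) * Inf) else jk$mean / jk$se
  structure(list(
    d = jk$mean, se = jk$se, z = z,
    p = 2 * pnorm(-abs(z)), n_blocks = jk$n_blocks, n_sites = length(idx)
  ), class = "dTest")
}

#' @export
print.dTest <- function(x, ...) {
  cat(sprintf("Patterson's D = %.3f +/- %.3f (Z = %.2f, p = %.3g, %d blocks)\n",
    x$d, x$se, x$z, x$p, x$n_blocks))
  invisible(x)
}

#' Three-population branch lengths at a locus
#'
#' Decomposes pairwise divergence among three groups (e.g. duplication
#' carriers, wild-type population A, wild-type population B) into
#' per-group branch lengths, analogously to the population branch
#' statistic: L_X = (T_XY + T_XZ - T_YZ)/2 with T = -log(1 - FST),
#' computed in non-overlapping windows of `windowSize` variants. Region
#' averages carry a block-jackknife SE over windows. A shorter wild-type
#' branch to the duplication group marks that group as the likely donor.
#'
#' @param countsX,countsY,countsZ Per-variant (ref, alt) count matrices.
#' @param windowSize Variants per window (default 100).
#' @param labels Group labels for the output.
#' @return List with `windows` (data.frame of per-window `l_<label>` and
#'   pairwise T columns) and `average` (data.frame: label, mean branch
#'   length, jackknife SE).
#' @export
threePopBranchLengths <- function(countsX, countsY, countsZ,
                                  windowSize = 100L,
                                  labels = c("X", "Y", "Z")) {
  txy <- fstToT(hudsonFst(countsX, countsY, windowSize)$value)
  txz <- fstToT(hudsonFst(countsX, countsZ, windowSize)$value)
  tyz <- fstToT(hudsonFst(countsY, countsZ, windowSize)$value)
  w <- windowFrame(windowStarts(nrow(countsX), windowSize), windowSize)
  w$t_xy <- txy; w$t_xz <- txz; w$t_yz <- tyz
  L <- cbind(
    (txy + txz - tyz) / 2,
    (txy + tyz - txz) / 2,
    (txz + tyz - txy) / 2
  )
  colnames(L) <- paste0("l_", labels)
  avg <- lapply(seq_len(3L), function(i) {
    v <- L[, i]
    v <- v[!is.na(v)]
    jk <- blockJackknifeMean(values = v, blockLength = 1L)
    data.frame(group = labels[i], mean = jk$mean, se = jk$se)
  })
  list(windows = cbind(w, L), average = do.call(rbind, avg))
}
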