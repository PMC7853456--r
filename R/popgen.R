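## Windowed differentiation scans. All window arithmetic is over 0-based
## half-open runs of consecutive variants ("windows of N variants", the
## convention for dense resequencing data); trailing partial windows are
## dropped.

altFreqAndN <- function(counts) {
  counts <- as.matrix(counts)
  n <- counts[, 1] + counts[, 2]
  list(p = ifelse(n > 0, counts[, 2] / n, NA_real_), n = n)
}

## Per-site Hudson FST components (estimator of Hudson 1992 as popularised
## for ratio-of-sums averaging): num = (p1-p2)^2 - p1(1-p1)/(n1-1)
## - p2(1-p2)/(n2-1); den = p1(1-p2) + p2(1-p1).
hudsonComponents <- function(countsA, countsB) {
  a <- altFreqAndN(countsA); b <- altFreqAndN(countsB)
  p1 <- a$p; p2 <- b$p; n1 <- a$n; n2 <- b$n
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  bad <- n1 < 2 | n2 < 2 | is.na(p1) | is.na(p2)
  num[bad] <- NA_real_; den[bad] <- NA_real_
  list(num = num, den = den)
}

windowStarts <- function(nSites, size, step = size) {
  if (size < 1L) stop("window size must be >= 1")
  starts <- seq(0L, nSites - size, by = as.integer(step))
  if (nSites < size) integer(0) else as.integer(starts)
}

windowFrame <- function(starts, size, positions = NULL) {
  d <- data.frame(
    window_index = seq_along(starts),
    first_variant = starts,          # 0-based inclusive
    last_variant = starts + size - 1L
  )
  if (!is.null(positions)) {
    d$first_pos <- positions[d$first_variant + 1L]
    d$last_pos <- positions[d$last_variant + 1L]
  }
  d
}

#' Windowed Hudson's FST between two populations
#'
#' Ratio-of-sums estimator over non-overlapping windows of consecutive
#' variants: each window's value is the sum of per-site numerators over the
#' sum of per-site denominators. Windows where a population has fewer than
#' two called alleles at every site are returned as `NA` (flagged
#' undefined).
#'
#' @param countsA,countsB Per-variant (ref, alt) allele-count matrices (one
#'   row per shared variant) as from [alleleCounts()].
#' @param windowSize Number of variants per window.
#' @param positions Optional 1-based variant positions for window
#'   coordinates.
#' @return data.frame of windows with column `value` (FST).
#' @export
hudsonFst <- function(countsA, countsB, windowSize = 1000L, positions = NULL) {
  stopifnot(nrow(countsA) == nrow(countsB))
  comp <- hudsonComponents(countsA, countsB)
  starts <- windowStarts(nrow(countsA), windowSize)
  out <- windowFrame(starts, windowSize, positions)
  out$value <- vapply(starts, function(s) {
    i <- (s + 1L):(s + windowSize)
    num <- sum(comp$num[i], na.rm = TRUE)
    den <- sum(comp$den[i], na.rm = TRUE)
    if (all(is.na(comp$den[i])) || den == 0) NA_real_ else num / den
  }, numeric(1))
  out
}

## -log(1 - FST) branch-length transform, clamped just below 1.
fstToT <- function(fst, clamp = 1 - 1e-12) {
  if (any(fst >= 1, na.rm = TRUE)) warning("FST >= 1 clamped before -log(1 - FST)")
  -log(1 - pmin(fst, clamp))
}

#' Windowed population branch statistic
#'
#' For each window, pairwise Hudson FST values are transformed to branch
#' lengths T = -log(1 - FST) and combined as
#' PBS_A = (T_AB + T_AC - T_BC) / 2, measuring allele-frequency change on
#' the branch leading to population A since its split from B, polarised by
#' outgroup C.
#'
#' @param countsA Focal population allele counts.
#' @param countsB Close reference population.
#' @param countsC Outgroup population.
#' @inheritParams hudsonFst
#' @return data.frame of windows with `value` (PBS of A) plus the three
#'   pairwise T columns `t_ab`, `t_ac`, `t_bc`.
#' @export
pbsScan <- function(countsA, countsB, countsC, windowSize = 1000L,
                    positions = NULL) {
  ab <- hudsonFst(countsA, countsB, windowSize, positions)
  ac <- hudsonFst(countsA, countsC, windowSize)
  bc <- hudsonFst(countsB, countsC, windowSize)
  out <- ab
  out$t_ab <- fstToT(ab$value)
  out$t_ac <- fstToT(ac$value)
  out$t_bc <- fstToT(bc$value)
  out$value <- (out$t_ab + out$t_ac - out$t_bc) / 2
  out
}

#' Standardise a windowed scan and attach FDR-corrected significance
#'
#' Standardises window values to zero mean and unit variance over the
#' scanned region, derives two-sided normal p-values from the Z-scores,
#' and corrects for multiple testing (Benjamini-Hochberg by default, or a
#' two-component empirical-null local FDR). The significant set is
#' standardised value > 0 and FDR below the threshold.
#'
#' @param scan data.frame with a `value` column (e.g. from [pbsScan()]).
#' @param fdrThreshold Significance threshold on the FDR (default 0.001).
#' @param method `"BH"` (tail-based Benjamini-Hochberg q-values) or
#'   `"local"` (empirical-null local FDR; see Details).
#' @details The local method fits a standard-normal null to the central
#'   half of the Z distribution (null proportion estimated from the
#'   interquartile mass) and a kernel estimate of the mixture density;
#'   fdr(z) = pi0 phi(z) / f(z), capped at 1.
#' @return Input with `z`, `p`, `fdr`, `significant` columns; attributes
#'   `mean` and `sd` hold the standardisation parameters.
#' @export
standardiseAndFdr <- function(scan, fdrThreshold = 0.001, method = c("BH", "local")) {
  method <- match.arg(method)
  v <- scan$value
  ok <- !is.na(v)
  if (sum(ok) < 20L) stop("need at least 20 windows to standardise a scan")
  mu <- mean(v[ok]); s <- sd(v[ok])
  if (s == 0) stop("zero variance across windows: cannot standardise")
  z <- (v - mu) / s
  p <- 2 * pnorm(-abs(z))
  fdr <- rep(NA_real_, length(v))
  if (method == "BH") {
    fdr[ok] <- p.adjust(p[ok], method = "BH")
  } else {
    fdr[ok] <- localFdr(z[ok])
  }
  scan$z <- z
  scan$p <- p
  scan$fdr <- fdr
  scan$significant <- !is.na(fdr) & z > 0 & fdr < fdrThreshold
  attr(scan, "mean") <- mu
  attr(scan, "sd") <- s
  scan
}

## Empirical-null local FDR: pi0 from the central mass, mixture density by
## Gaussian kernel; fdr(z) = pi0 phi(z) / f(z), capped at 1.
localFdr <- function(z) {
  pi0 <- min(1, mean(abs(z) <= stats::qnorm(0.75)) / 0.5)
  dens <- stats::density(z, n = 1024)
  f <- stats::approx(dens$x, dens$y, xout = z, rule = 2)$y
  pmin(1, pi0 * dnorm(z) / pmax(f, .Machine$double.eps))
}

#' Block-jackknife mean and standard error
#'
#' Splits a value vector into consecutive blocks of `blockLength`
#' (trailing remainder joins the last block), recomputes the mean leaving
#' one block out at a time, and returns the delete-one jackknife SE
#' `sqrt((B-1)/B * sum((theta_i - mean(theta))^2))`.
#'
#' @param values Numeric vector (per-variant or per-window contributions).
#' @param blockLength Variants per block.
#' @param num,den Alternative ratio-of-sums input: per-site numerator and
#'   denominator vectors (overrides `values`; the statistic is
#'   sum(num)/sum(den)).
#' @return List with `mean`, `se`, `n_blocks`.
#' @export
blockJackknifeMean <- function(values = NULL, blockLength, num = NULL, den = NULL) {
  ratio <- !is.null(num)
  if (ratio) {
    stopifnot(length(num) == length(den))
    n <- length(num)
  } else n <- length(values)
  nb <- n %/% blockLength
  if (nb < 2L) stop("need at least 2 blocks for the jackknife")
  block <- pmin((seq_len(n) - 1L) %/% blockLength + 1L, nb)
  if (ratio) {
    sn <- tapply(num, block, sum, na.rm = TRUE)
    sdn <- tapply(den, block, sum, na.rm = TRUE)
    est <- sum(sn) / sum(sdn)
    loo <- (sum(sn) - sn) / (sum(sdn) - sdn)
  } else {
    sb <- tapply(values, block, sum)
    cb <- tabulate(block, nb)
    est <- sum(sb) / n
    loo <- (sum(sb) - sb) / (n - cb)
  }
  se <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
  list(mean = est, se = se, n_blocks = nb)
}

#' LD pruning by Rogers-Huff r within sliding base-pair windows
#'
#' Scans windows of `windowBp` advanced by `stepBp`; within each window a
#' variant is dropped when its squared dosage correlation with an earlier
#' retained variant exceeds `rThreshold^2`. The pass is repeated
#' `iterations` times (a fixed point is reached at or before that).
#'
#' @param dos Variant x sample dosage matrix (0/1/2, `NA` allowed).
#' @param positions 1-based variant positions.
#' @param windowBp,stepBp Window and step sizes in bp.
#' @param rThreshold Rogers-Huff |r| threshold (default 0.1).
#' @param iterations Number of pruning passes (default 10).
#' @return Integer indices of retained variants (ascending).
#' @export
ldPrune <- function(dos, positions, windowBp = 500L, stepBp = 200L,
                    rThreshold = 0.1, iterations = 10L) {
  keep <- seq_len(nrow(dos))
  for (it in seq_len(iterations)) {
    pos <- positions[keep]
    drop <- logical(length(keep))
    starts <- seq(min(pos), max(pos), by = stepBp)
    for (ws in starts) {
      inw <- which(pos >= ws & pos < ws + windowBp & !drop)
      if (length(inw) < 2L) next
      for (a in seq_along(inw)[-1L]) {
        for (b in seq_len(a - 1L)) {
          if (drop[inw[b]]) next
          r <- rogersHuffR(dos[keep[inw[b]], ], dos[keep[inw[a]], ])
          if (!is.na(r) && r^2 > rThreshold^2) { drop[inw[a]] <- TRUE; break }
        }
      }
    }
    if (!any(drop)) break
    keep <- keep[!drop]
  }
  keep
}

#' PCA of genotype dosages with Patterson scaling
#'
#' Centres each variant's dosage at its mean and scales by
#' `sqrt(p(1-p))` with p the alternate-allele frequency (mean dosage / 2),
#' then decomposes by SVD. Coordinates are left singular vectors times
#' singular values. Monomorphic variants carry no information and are
#' excluded with a warning; missing dosages are mean-imputed (centred to
#' zero) for the decomposition only.
#'
#' @param dos Variant x sample dosage matrix.
#' @param nComponents Number of components to return.
#' @return List with `coords` (sample x component), `singular_values`,
#'   `kept` (variant indices used).
#' @export
pcaPatterson <- function(dos, nComponents = 10L) {
  stopifnot(nrow(dos) >= 2L, ncol(dos) >= 2L)
  mu <- rowMeans(dos, na.rm = TRUE)
  p <- mu / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) warning(sum(!poly), " monomorphic variant(s) excluded from PCA")
  x <- dos[poly, , drop = FALSE]
  mu <- mu[poly]; p <- p[poly]
  x <- sweep(x, 1L, mu)
  x[is.na(x)] <- 0
  x <- sweep(x, 1L, sqrt(p * (1 - p)), "/")
  sv <- svd(t(x))
  k <- min(nComponents, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- colnames(dos)
  list(coords = coords, singular_values = sv$d[seq_len(k)], kept = which(poly))
}
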