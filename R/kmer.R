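## k-mer genotype-phenotype association: canonical counting with 2-bit
## integer codes, presence/absence variance filtering, per-sample frequency
## normalisation, Spearman association against a binary phenotype with FDR
## control, greedy perfect-overlap assembly of significant k-mers,
## exact-match placement on a reference, and a copy-number residual
## correlation diagnostic for contigs placed away from the locus.

#' Encode k-mers as canonical 2-bit-packed integer codes
#'
#' A = 0, C = 1, G = 2, T = 3, first base most significant; the canonical
#' code is the smaller of the k-mer's code and its reverse complement's.
#' Codes are returned as decimal strings because 62-bit values (k = 31)
#' exceed R's exact integer range.
#'
#' @param kmers Character vector of k-mers (all length `k`).
#' @param k K-mer length (<= 31).
#' @param canonical Canonicalise (default) or encode as-is.
#' @return Character vector of decimal codes; `NA` for k-mers containing
#'   non-ACGT characters.
#' @export
kmerEncode <- function(kmers, k = unique(nchar(kmers)), canonical = TRUE) {
  stopifnot(length(k) == 1L, k >= 1L, k <= 31L)
  kl <- min(15L, as.integer(k))
  vapply(as.character(kmers), function(s) {
    if (nchar(s) != k) return(NA_character_)
    b <- baseCodes(s)
    hl <- if (canonical) canonicalHiLo(b, as.integer(k))
          else kmerHiLo(b, as.integer(k))
    hiLoToDecimal(hl[1, 1], hl[1, 2], kl)
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname kmerEncode
#' @param codes Decimal code strings.
#' @export
kmerDecode <- function(codes, k) {
  k <- as.integer(k)
  kl <- min(15L, k)
  vapply(as.character(codes), function(cd) {
    if (is.na(cd)) return(NA_character_)
    hl <- decimalToHiLo(cd, kl)
    hiLoToKmer(hl[["hi"]], hl[["lo"]], k)
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of character sequences
#'
#' @param seqs Character vector of A/C/G/T/N sequences.
#' @return Reverse-complemented sequences.
#' @export
revComp <- function(seqs) {
  vapply(seqs, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Count canonical k-mers per sample
#'
#' Counts canonical k-mers (lexicographic minimum of each k-mer and its
#' reverse complement) in one FASTA/character read set per sample. k-mers
#' spanning a non-ACGT character are skipped; reads shorter than k are
#' tallied, not an error.
#'
#' @param reads Named list: one character vector of reads (or a FASTA path)
#'   per sample.
#' @param k K-mer length (odd, <= 31 so codes fit 2-bit packing in 64-bit
#'   words; default 31).
#' @return A [KmerTable-class] with all retained flags `TRUE` pending
#'   filtering.
#' @export
countKmers <- function(reads, k = 31L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k > 31L || k < 1L)
    stop("k must be odd and at most 31 under 2-bit packing")
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must be a named list with unique sample names")
  kl <- min(15L, k)
  per <- lapply(reads, function(r) {
    if (length(r) == 1L && file.exists(r) && grepl("\\.(fa|fasta|fq|fastq)$", r))
      r <- readFastaRecords(r, strict = FALSE)
    r <- as.character(r)
    short <- sum(nchar(r) < k)
    keys <- unlist(lapply(r[nchar(r) >= k], function(s) {
      hl <- canonicalHiLo(baseCodes(s), k)
      ok <- !is.na(hl[, 1])
      sprintf("%.0f_%.0f", hl[ok, 1], hl[ok, 2])
    }), use.names = FALSE)
    tab <- table(keys)
    list(key = names(tab), count = as.integer(tab), short_reads = short)
  })
  keys <- unique(unlist(lapply(per, `[[`, "key"), use.names = FALSE))
  if (length(keys)) {
    hl <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
    hi <- as.numeric(hl[, 1]); lo <- as.numeric(hl[, 2])
    ord <- order(hi, lo)
    keys <- keys[ord]
    codes <- hiLoToDecimal(hi[ord], lo[ord], kl)
  } else codes <- character(0)
  counts <- matrix(0L, length(codes), length(per),
                   dimnames = list(NULL, names(reads)))
  for (j in seq_along(per)) {
    i <- match(per[[j]]$key, keys)
    counts[i, j] <- per[[j]]$count
  }
  new("KmerTable", k = k, codes = codes, counts = counts,
      retained = rep(TRUE, length(codes)),
      sampleTotals = rep(NA_real_, length(per)),
      shortReads = vapply(per, function(x) as.integer(x$short_reads), integer(1)))
}

#' Filter k-mers to those varying across the cohort
#'
#' Retains a k-mer iff it is present (count > 0) in at least `minPresent`
#' samples and absent (count == 0) in at least `minAbsent` samples; k-mers
#' shared by everyone or nearly private carry no association information.
#' Per-sample normalisation totals are recomputed as the sums of retained
#' counts.
#'
#' @param tab A [KmerTable-class].
#' @param minPresent,minAbsent Inclusive sample-count bounds (default 3).
#' @param totalsFrom Denominator convention: `"retained"` (default) sums
#'   counts of retained k-mers only; `"all"` sums every counted k-mer.
#' @return The table with updated `retained` flags and `sampleTotals`.
#' @export
filterVariantKmers <- function(tab, minPresent = 3L, minAbsent = 3L,
                               totalsFrom = c("retained", "all")) {
  stopifnot(is(tab, "KmerTable"))
  totalsFrom <- match.arg(totalsFrom)
  ns <- ncol(tab@counts)
  if (ns < minPresent + minAbsent)
    stop("need at least minPresent + minAbsent samples")
  present <- rowSums(tab@counts > 0L)
  tab@retained <- present >= minPresent & (ns - present) >= minAbsent
  tab@sampleTotals <- if (totalsFrom == "retained")
    colSums(tab@counts[tab@retained, , drop = FALSE])
  else colSums(tab@counts)
  tab
}

#' Normalised k-mer frequencies
#'
#' @param tab A filtered [KmerTable-class].
#' @return Matrix (retained k-mer x sample) of counts divided by the
#'   per-sample totals; rownames are the k-mer codes.
#' @export
kmerFrequencies <- function(tab) {
  stopifnot(is(tab, "KmerTable"))
  if (anyNA(tab@sampleTotals)) stop("run filterVariantKmers() first")
  f <- sweep(tab@counts[tab@retained, , drop = FALSE], 2L,
             pmax(tab@sampleTotals, 1), "/")
  rownames(f) <- tab@codes[tab@retained]
  f
}

## Spearman rho with midranks; exact permutation p over the distinct
## binary-phenotype assignments for n <= exactN, t-approximation otherwise.
spearmanBinary <- function(f, y, exactN = 10L) {
  n <- length(y)
  rf <- rank(f)
  rho <- suppressWarnings(cor(rf, rank(y)))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (n <= exactN) {
    ones <- sum(y)
    sets <- combn(n, ones)
    obs <- abs(rho)
    rhos <- apply(sets, 2L, function(ix) {
      yy <- integer(n); yy[ix] <- 1L
      suppressWarnings(cor(rf, rank(yy)))
    })
    p <- mean(abs(rhos) >= obs - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p)
}

#' Associate k-mer frequencies with a binary phenotype
#'
#' Spearman rank correlation (midranks for ties) of each retained k-mer's
#' normalised frequency with the 0/1 phenotype, with FDR correction and a
#' significance call at `fdrThreshold`. k-mers with constant frequency
#' across samples have no defined rank correlation and are excluded (the
#' number excluded is reported as an attribute).
#'
#' @param tab Filtered [KmerTable-class].
#' @param phenotype Named or ordered 0/1 vector aligned with the table's
#'   samples.
#' @param fdrThreshold Default 0.001.
#' @param fdrMethod `"BH"` or `"local"` (see [standardiseAndFdr()]).
#' @return data.frame: `code`, `rho`, `p`, `fdr`, `significant`;
#'   attribute `n_constant` tallies excluded constant k-mers.
#' @export
kmerAssociate <- function(tab, phenotype, fdrThreshold = 0.001,
                          fdrMethod = c("BH", "local")) {
  fdrMethod <- match.arg(fdrMethod)
  f <- kmerFrequencies(tab)
  if (!is.null(names(phenotype)))
    phenotype <- phenotype[colnames(f)]
  stopifnot(length(phenotype) == ncol(f), all(phenotype %in% 0:1))
  if (nrow(f) == 0L) {
    out <- data.frame(code = character(), rho = numeric(), p = numeric(),
                      fdr = numeric(), significant = logical())
    attr(out, "n_constant") <- 0L
    return(out)
  }
  res <- t(apply(f, 1L, spearmanBinary, y = phenotype))
  out <- data.frame(code = rownames(f), rho = res[, "rho"], p = res[, "p"],
                    row.names = NULL, stringsAsFactors = FALSE)
  keep <- !is.na(out$rho)
  out <- out[keep, , drop = FALSE]
  out$fdr <- if (fdrMethod == "BH") p.adjust(out$p, "BH")
             else localFdr(qnorm(pmax(pmin(out$p / 2, 0.5 - 1e-12), 1e-300)) * -sign(out$rho))
  out$significant <- out$fdr < fdrThreshold
  attr(out, "n_constant") <- sum(!keep)
  out
}

overlapLen <- function(a, b, minOverlap) {
  ## longest suffix of a equal to prefix of b, >= minOverlap
  max_o <- min(nchar(a), nchar(b))
  for (o in max_o:minOverlap) {
    if (substr(a, nchar(a) - o + 1L, nchar(a)) == substr(b, 1L, o)) return(o)
  }
  0L
}

#' Assemble significant k-mers by perfect overlap
#'
#' Greedy merging: among all ordered pairs of current sequences (either
#' orientation), repeatedly merge the pair with the longest perfect
#' suffix/prefix overlap of at least `minOverlap` bp (ties broken by
#' lexicographic order of the merged pair), until no pair overlaps.
#' Containments (one sequence a substring of another, either strand)
#' are absorbed first.
#'
#' @param kmers Character vector of significant k-mer sequences.
#' @param minOverlap Minimum perfect overlap (default 10).
#' @return data.frame with `contig` (sequence, in the orientation of its
#'   first member) and `members` (list-column of member k-mers).
#' @export
assembleSignificant <- function(kmers, minOverlap = 10L) {
  if (!length(kmers))
    return(data.frame(contig = character(), members = I(list())))
  seqs <- as.character(kmers)
  members <- lapply(seqs, function(x) x)
  repeat {
    n <- length(seqs)
    if (n < 2L) break
    ## absorb containments
    absorbed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (grepl(seqs[i], seqs[j], fixed = TRUE) ||
            grepl(revComp(seqs[i]), seqs[j], fixed = TRUE)) {
          members[[j]] <- c(members[[j]], members[[i]])
          seqs <- seqs[-i]; members <- members[-i]
          absorbed <- TRUE
          break
        }
      }
      if (absorbed) break
    }
    if (absorbed) next
    ## best overlap over ordered pairs and orientations
    best <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        for (orient in c("ff", "fr")) {
          b <- if (orient == "ff") seqs[j] else revComp(seqs[j])
          o <- overlapLen(seqs[i], b, minOverlap)
          if (o >= minOverlap) {
            cand <- list(i = i, j = j, o = o, b = b)
            if (is.null(best) || o > best$o ||
                (o == best$o &&
                 paste(seqs[i], b) < paste(seqs[best$i], best$b)))
              best <- cand
          }
        }
      }
    }
    if (is.null(best)) break
    merged <- paste0(seqs[best$i],
                     substr(best$b, best$o + 1L, nchar(best$b)))
    mem <- c(members[[best$i]], members[[best$j]])
    keep <- setdiff(seq_len(n), c(best$i, best$j))
    seqs <- c(seqs[keep], merged)
    members <- c(members[keep], list(mem))
  }
  data.frame(contig = seqs, members = I(members), stringsAsFactors = FALSE)
}

#' Place contigs on a reference by exact matching
#'
#' Exact substring search on both strands; every hit is reported. Contigs
#' without a hit are returned with `NA` coordinates and `placed = FALSE`.
#'
#' @param contigs Character vector of assembled sequences.
#' @param reference Named character vector of reference sequences (from
#'   [readFastaRecords()]).
#' @return data.frame: `contig_index`, `ref`, `start` (1-based), `strand`,
#'   `placed`.
#' @export
placeContigs <- function(contigs, reference) {
  rows <- list()
  refSet <- Biostrings::DNAStringSet(reference)
  for (ci in seq_along(contigs)) {
    hit <- FALSE
    for (strand in c("+", "-")) {
      q <- if (strand == "+") contigs[ci] else revComp(contigs[ci])
      for (ri in seq_along(refSet)) {
        m <- Biostrings::matchPattern(q, refSet[[ri]])
        if (length(m)) {
          hit <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            contig_index = ci, ref = names(reference)[ri],
            start = Biostrings::start(m), strand = strand, placed = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!hit)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_index = ci, ref = NA_character_, start = NA_integer_,
        strand = NA_character_, placed = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Copy-number residual correlation for a contig
#'
#' A contig correlated with the phenotype is expected to correlate with
#' locus copy number even if physically unlinked, because both track the
#' phenotype. To control for that, contig frequency and copy number are
#' residualised about their group means within each phenotype class, the
#' residuals pooled, and Pearson's correlation computed on them; a
#' physically linked contig remains correlated after this adjustment.
#'
#' @param freq Per-sample contig frequency (mean normalised frequency of
#'   member k-mers).
#' @param copyNumber Per-sample locus copy number.
#' @param phenotype Per-sample 0/1 class; each class needs >= 3 samples.
#' @return List with `r` and `p` (two-sided, t-distribution).
#' @export
copyNumberResidualCorrelation <- function(freq, copyNumber, phenotype) {
  stopifnot(length(freq) == length(copyNumber),
            length(freq) == length(phenotype))
  if (any(table(factor(phenotype, levels = 0:1)) < 3L))
    stop("each phenotype group needs at least 3 samples")
  rf <- freq - ave(freq, phenotype)
  rc <- copyNumber - ave(copyNumber, phenotype)
  if (sd(rf) == 0 || sd(rc) == 0) stop("degenerate residuals: zero variance")
  r <- cor(rf, rc)
  n <- length(freq)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Mean normalised frequency of a contig's member k-mers
#'
#' @param tab Filtered [KmerTable-class].
#' @param members Character vector of member k-mer sequences.
#' @return Per-sample mean frequency vector.
#' @export
contigFrequency <- function(tab, members) {
  f <- kmerFrequencies(tab)
  codes <- kmerEncode(members, k = tab@k)
  i <- match(codes, rownames(f))
  if (anyNA(i)) stop("member k-mer not present among retained k-mers")
  colMeans(f[i, , drop = FALSE])
}
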