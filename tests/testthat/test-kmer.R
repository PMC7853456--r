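test_that("2-bit encode/decode round-trips exhaustively at small k and at k = 31", {
  ## exhaustive at k = 1, 3, 5 (non-canonical: pure packing identity)
  for (k in c(1L, 3L, 5L)) {
    all_kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k)))
    codes <- kmerEncode(all_kmers, k = k, canonical = FALSE)
    expect_false(anyDuplicated(codes) > 0)
    expect_identical(kmerDecode(codes, k), all_kmers)
  }
  ## random 31-mers: canonical code decodes to min(kmer, revcomp)
  set.seed(19)
  for (i in 1:50) {
    km <- paste(sample(c("A", "C", "G", "T"), 31, replace = TRUE), collapse = "")
    canon <- min(km, revComp(km))
    expect_identical(kmerDecode(kmerEncode(km), 31L), canon)
    ## a k-mer and its reverse complement share one canonical code
    expect_identical(kmerEncode(km), kmerEncode(revComp(km)))
  }
  expect_true(is.na(kmerEncode("ACGTN", k = 5L)))
})

test_that("canonical counting is strand- and order-independent with exact totals", {
  k1 <- countKmers(list(s = "AAAAA"), k = 3L)
  expect_equal(k1@codes, kmerEncode("AAA"))
  expect_equal(as.integer(k1@counts), 3L)

  set.seed(3)
  seq1 <- randomSequence(1000, seed = 3)
  kA <- countKmers(list(s = seq1), k = 7L)
  kB <- countKmers(list(s = revComp(seq1)), k = 7L)
  expect_equal(kA@codes, kB@codes)
  expect_equal(kA@counts, kB@counts)
  ## total instances = L - k + 1
  expect_equal(sum(kA@counts), 1000L - 7L + 1L)
  ## N-containing windows are skipped
  seqN <- paste0(substr(seq1, 1, 100), "N", substr(seq1, 102, 200))
  kN <- countKmers(list(s = seqN), k = 7L)
  expect_equal(sum(kN@counts), (200L - 7L + 1L) - 7L)

  ## shuffling reads leaves the table invariant
  reads <- substring(seq1, seq(1, 901, by = 50), seq(100, 1000, by = 50))
  t1 <- countKmers(list(s = reads), k = 9L)
  t2 <- countKmers(list(s = rev(reads)), k = 9L)
  expect_equal(t1@codes, t2@codes)
  expect_equal(t1@counts, t2@counts)

  ## short reads are tallied, not fatal
  t3 <- countKmers(list(s = c("ACGT", seq1)), k = 31L)
  expect_equal(unname(t3@shortReads), 1L)
})

test_that("variance filter keeps k-mers present in >= 3 and absent in >= 3 samples", {
  counts <- rbind(
    c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),  # present in 2: dropped
    rep(1, 10),                       # present in all: dropped
    c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),  # present 3 / absent 7: retained
    c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0)   # absent in 2: dropped
  )
  tab <- new("KmerTable", k = 5L, codes = as.character(1:4),
             counts = matrix(as.integer(counts), 4, 10,
                             dimnames = list(NULL, paste0("s", 1:10))),
             retained = rep(TRUE, 4), sampleTotals = rep(NA_real_, 10),
             shortReads = integer(10))
  out <- filterVariantKmers(tab)
  expect_identical(out@retained, c(FALSE, FALSE, TRUE, FALSE))
  ## retained-denominator convention: per-sample totals over retained rows
  expect_equal(unname(out@sampleTotals), as.numeric(counts[3, ]))
  freq <- kmerFrequencies(out)
  expect_true(all(freq[, 1:3] == 1))
  expect_error(filterVariantKmers(tab, minPresent = 6, minAbsent = 6), "samples")
})

test_that("Spearman association finds truth, stays null-calibrated, flags constants", {
  set.seed(8)
  n <- 20
  y <- rep(c(1L, 0L), each = n / 2)
  ## noise k-mers: random presence/absence, uncorrelated with phenotype;
  ## signal k-mer: present only in phenotype-1 samples (after the variance
  ## filter both kinds survive, but only the signal tracks the phenotype)
  counts <- rbind(
    matrix(rbinom(50 * n, 1, 0.5) * rpois(50 * n, 10), ncol = n),
    y * rpois(n, 20) + y
  )
  tab <- new("KmerTable", k = 5L, codes = as.character(seq_len(nrow(counts))),
             counts = matrix(as.integer(counts), nrow(counts), n,
                             dimnames = list(NULL, paste0("s", 1:n))),
             retained = rep(TRUE, nrow(counts)),
             sampleTotals = rep(NA_real_, n), shortReads = integer(n))
  tab <- filterVariantKmers(tab)
  res <- kmerAssociate(tab, y, fdrThreshold = 0.001)
  sig <- res$code[res$significant]
  expect_true(as.character(nrow(counts)) %in% sig)

  ## permutation null: phenotype shuffled, nothing significant
  set.seed(31)
  resNull <- kmerAssociate(tab, sample(y), fdrThreshold = 0.001)
  expect_equal(sum(resNull$significant), 0L)
})

test_that("exact permutation p is used for small cohorts and matches enumeration", {
  y <- c(1, 1, 1, 0, 0, 0)
  f <- c(10, 9, 8, 1, 2, 3) / 33
  p <- dupsweep:::spearmanBinary(f, y)
  ## perfectly separating frequency: 2 of choose(6,3)=20 assignments reach |rho|
  expect_equal(unname(p["p"]), 2 / 20)
  expect_equal(unname(p["rho"]), cor(rank(f), rank(y)))
})

test_that("assembly merges on >= 10 bp perfect overlap and round-trips a shredding", {
  x <- randomSequence(60, seed = 44)
  kmers31 <- substring(x, 1:30, 31:60)
  asm <- assembleSignificant(kmers31, minOverlap = 10L)
  expect_equal(nrow(asm), 1L)
  expect_true(asm$contig[1] == x || asm$contig[1] == revComp(x))
  expect_length(asm$members[[1]], 30L)

  ## two 31-mers overlapping by 30 bp merge into a 32 bp contig
  two <- c(substr(x, 1, 31), substr(x, 2, 32))
  asm2 <- assembleSignificant(two)
  expect_equal(nrow(asm2), 1L)
  expect_equal(nchar(asm2$contig[1]), 32L)

  ## 9 bp overlap: below threshold, no merge
  a <- paste0(randomSequence(22, seed = 1), "ACGTACGTA")
  b <- paste0("ACGTACGTA", randomSequence(22, seed = 2))
  asm3 <- assembleSignificant(c(a, b))
  expect_equal(nrow(asm3), 2L)

  ## orientation-aware: a read and a reverse-complemented overlapper merge
  c1 <- substr(x, 1, 31); c2 <- revComp(substr(x, 12, 42))
  asm4 <- assembleSignificant(c(c1, c2))
  expect_equal(nrow(asm4), 1L)
  expect_equal(nchar(asm4$contig[1]), 42L)
})

test_that("contigs place by exact match on either strand or are marked unplaced", {
  ref <- c(chr1 = randomSequence(10000, seed = 55))
  contig <- substr(ref[[1]], 101, 160)
  pl <- placeContigs(c(contig, revComp(contig)), ref)
  expect_equal(pl$start[pl$contig_index == 1], 101L)
  expect_equal(pl$strand[pl$contig_index == 1], "+")
  expect_equal(pl$start[pl$contig_index == 2], 101L)
  expect_equal(pl$strand[pl$contig_index == 2], "-")

  rand40 <- randomSequence(40, seed = 77)
  pl2 <- placeContigs(rand40, ref)
  expect_false(any(pl2$placed))
})

test_that("copy-number residual correlation separates linkage from phenotype confounding", {
  set.seed(9)
  n <- 40
  y <- rep(c(1, 0), each = n / 2)
  C <- rpois(n, 3) + 1 + 2 * y            # copy number tracks phenotype
  ## physically linked contig: frequency proportional to copy number
  fLinked <- 0.01 * C
  rc <- copyNumberResidualCorrelation(fLinked, C, y)
  expect_equal(rc$r, 1, tolerance = 1e-9)
  expect_lt(rc$p, 1e-6)

  ## unlinked contig: frequency depends only on phenotype; residual r ~ 0
  rs <- replicate(200, {
    fUnlinked <- 0.02 * y + rnorm(n, 0, 0.002)
    copyNumberResidualCorrelation(fUnlinked, C, y)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
  ## and its null spread matches a phenotype-stratified permutation null
  perm <- replicate(200, {
    fUnlinked <- 0.02 * y + rnorm(n, 0, 0.002)
    Cp <- C
    Cp[y == 1] <- sample(C[y == 1])
    Cp[y == 0] <- sample(C[y == 0])
    copyNumberResidualCorrelation(fUnlinked, Cp, y)$r
  })
  expect_lt(abs(quantile(abs(rs), 0.95) - quantile(abs(perm), 0.95)), 0.15)
  expect_error(copyNumberResidualCorrelation(1:5, 1:5, c(1, 1, 1, 1, 0)),
               "3 samples")
})
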