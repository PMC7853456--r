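## Synthetic cohorts with the statistical structure the pipeline assumes:
## a tandem duplication carrying a resistance SNP on a swept haplotype,
## binomial allele-supporting read fractions, logistic survival in the
## resistant-allele dosage, three-population frequency structure with an
## optional introgressed tract, and per-sample read sets with or without
## the duplication junction.

## Run expr with its own RNG stream; the caller's .Random.seed is restored.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cohort simulation configuration
#'
#' Defaults emulate a field cohort at a duplicated resistance locus:
#' sequencing depth averaging 30x, locus copy numbers between 2 and 5,
#' resistant-haplotype frequency 0.44 (the focal SNP's frequency in the
#' motivating cohort), and logistic survival in the resistant dosage S
#' with intercept -2.5 and +1.2 per resistant copy (survival ~8% at S = 0
#' rising to ~88% at S = 4).
#'
#' @param nSamples Cohort size.
#' @param copyNumberProbs Named probability vector over copy numbers
#'   (names = integer C values, all >= 2... a C_max below 2 is a
#'   configuration error).
#' @param resistantHapFreq Per-copy probability of carrying the resistant
#'   allele; S | C ~ Binomial(C, freq).
#' @param depthMean Mean sequencing depth at the focal site (Poisson,
#'   truncated at 1 so every sample has coverage).
#' @param beta0,betaS Logistic phenotype coefficients:
#'   P(alive) = plogis(beta0 + betaS * S).
#' @param focalPosition 1-based position given to the focal SNP.
#' @param chrom Contig label.
#' @param seed RNG seed.
#' @return Validated config list of class `cohortSimConfig`.
#' @export
cohortSimConfig <- function(nSamples = 500L,
                            copyNumberProbs = c("2" = 0.35, "3" = 0.30,
                                                "4" = 0.25, "5" = 0.10),
                            resistantHapFreq = 0.44,
                            depthMean = 30,
                            beta0 = -2.5, betaS = 1.2,
                            focalPosition = 3500000L,
                            chrom = "2R", seed = 1L) {
  cvals <- as.integer(names(copyNumberProbs))
  if (anyNA(cvals) || max(cvals) < 2L)
    stop("copy-number support must be named by integers with C_max >= 2")
  if (abs(sum(copyNumberProbs) - 1) > 1e-8)
    stop("copy-number probabilities must sum to 1")
  if (depthMean <= 0) stop("depth must be positive")
  if (resistantHapFreq < 0 || resistantHapFreq > 1)
    stop("resistantHapFreq must be in [0, 1]")
  structure(list(nSamples = as.integer(nSamples),
                 copyNumberProbs = copyNumberProbs,
                 resistantHapFreq = resistantHapFreq,
                 depthMean = depthMean, beta0 = beta0, betaS = betaS,
                 focalPosition = as.integer(focalPosition),
                 chrom = chrom, seed = as.integer(seed)),
            class = "cohortSimConfig")
}

#' Simulate a phenotyped cohort at a duplicated resistance locus
#'
#' Each sample draws a locus copy number C from the configured
#' distribution and a resistant dosage S | C ~ Binomial(C, freq), so
#' 0 <= S <= C. Read support at the focal SNP is
#' alt ~ Binomial(depth, S/C) at a Poisson depth, and survival is
#' Bernoulli(plogis(beta0 + betaS * S)). Identical config and seed give
#' identical output.
#'
#' @param config A [cohortSimConfig()].
#' @return List: `genotypes` ([GenotypeMatrix-class] of the focal SNP with
#'   AD), `copyNumbers`, `phenotypes` (both io-format data.frames),
#'   `truth` (per-sample latent `C`, `S`, `depth`, `p_alive`).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "cohortSimConfig"))
  withLocalSeed(config$seed, {
    n <- config$nSamples
    ids <- sprintf("S%04d", seq_len(n))
    cvals <- as.integer(names(config$copyNumberProbs))
    C <- sample(cvals, n, replace = TRUE, prob = config$copyNumberProbs)
    S <- rbinom(n, C, config$resistantHapFreq)
    depth <- rpois(n, config$depthMean)
    depth[depth == 0L] <- 1L
    altR <- rbinom(n, depth, S / C)
    refR <- depth - altR
    pAlive <- stats::plogis(config$beta0 + config$betaS * S)
    phen <- rbinom(n, 1L, pAlive)
    ## diploid-style GT call at the focal site: 0/0, 0/1 or 1/1
    a1 <- as.integer(S == C)
    a2 <- as.integer(S > 0L)
    gm <- GenotypeMatrix(config$chrom, config$focalPosition,
      allele1 = matrix(a1, 1L), allele2 = matrix(a2, 1L),
      refDepth = matrix(refR, 1L), altDepth = matrix(altR, 1L),
      sampleIds = ids)
    list(
      genotypes = gm,
      copyNumbers = data.frame(sample_id = ids, copy_number = C,
                               stringsAsFactors = FALSE),
      phenotypes = data.frame(sample_id = ids, phenotype = phen,
                              population = "sim", stringsAsFactors = FALSE),
      truth = data.frame(sample_id = ids, C = C, S = S, depth = depth,
                         alt_reads = altR, p_alive = pAlive,
                         phenotype = phen, stringsAsFactors = FALSE)
    )
  })
}

#' Sweep simulation configuration
#'
#' A copying model, not a coalescent: swept haplotypes are copies of one
#' core haplotype whose identity decays with distance from the focal
#' variant (per-site probability `recombScale` of switching permanently to
#' an independent background haplotype, plus per-site mutation), while
#' background haplotypes are drawn independently from Beta-distributed
#' site frequencies. The statistics profiled on the output (Garud's H,
#' EHH, diversity) depend only on this haplotype-identity structure.
#'
#' @param nHaplotypes,nVariants Dimensions of the output.
#' @param focalIndex 1-based index of the swept variant (default centre).
#' @param sweptFreq Frequency of the swept core haplotype, in (0, 1).
#' @param mutationProb Per-site flip probability on swept copies.
#' @param recombScale Per-site switch-to-background probability.
#' @param chrom,positionStart,positionStep Coordinates for the output.
#' @param seed RNG seed.
#' @export
sweepSimConfig <- function(nHaplotypes = 200L, nVariants = 500L,
                           focalIndex = NULL, sweptFreq = 0.6,
                           mutationProb = 0.002, recombScale = 0.01,
                           chrom = "2R", positionStart = 3400000L,
                           positionStep = 400L, seed = 1L) {
  if (is.null(focalIndex)) focalIndex <- as.integer(ceiling(nVariants / 2))
  if (sweptFreq <= 0 || sweptFreq > 1) stop("swept frequency must be in (0, 1]")
  if (focalIndex < 1L || focalIndex > nVariants) stop("focal index out of range")
  structure(list(nHaplotypes = as.integer(nHaplotypes),
                 nVariants = as.integer(nVariants),
                 focalIndex = as.integer(focalIndex), sweptFreq = sweptFreq,
                 mutationProb = mutationProb, recombScale = recombScale,
                 chrom = chrom, positionStart = as.integer(positionStart),
                 positionStep = as.integer(positionStep),
                 seed = as.integer(seed)),
            class = "sweepSimConfig")
}

#' Simulate haplotypes under a hard sweep (copying model)
#'
#' @param config A [sweepSimConfig()].
#' @return A [HaplotypeMatrix-class]; attribute `swept` flags the carrier
#'   haplotypes, which carry allele 1 at the focal variant.
#' @export
simulateSweep <- function(config) {
  stopifnot(inherits(config, "sweepSimConfig"))
  withLocalSeed(config$seed, {
    nv <- config$nVariants; nh <- config$nHaplotypes
    freqs <- rbeta(nv, 0.8, 0.8)
    nSwept <- round(config$sweptFreq * nh)
    core <- as.integer(runif(nv) < freqs)
    core[config$focalIndex] <- 1L
    drawBackground <- function() {
      b <- as.integer(runif(nv) < freqs)
      b[config$focalIndex] <- 0L
      b
    }
    h <- matrix(0L, nv, nh)
    for (j in seq_len(nh)) {
      if (j <= nSwept) {
        hap <- core
        bg <- drawBackground()
        for (side in c(1L, -1L)) {
          idx <- config$focalIndex + side
          copying <- TRUE
          while (idx >= 1L && idx <= nv) {
            if (copying && runif(1) < config$recombScale) copying <- FALSE
            if (!copying) hap[idx] <- bg[idx]
            idx <- idx + side
          }
        }
        mut <- runif(nv) < config$mutationProb
        mut[config$focalIndex] <- FALSE
        hap[mut] <- 1L - hap[mut]
        h[, j] <- hap
      } else {
        h[, j] <- drawBackground()
      }
    }
    hm <- HaplotypeMatrix(config$chrom,
      config$positionStart + (seq_len(nv) - 1L) * config$positionStep, h)
    attr(hm, "swept") <- seq_len(nh) <= nSwept
    hm
  })
}

#' Three-population simulation configuration
#'
#' Balding-Nichols structure: each site draws an ancestral frequency, and
#' each population's frequency is Beta-distributed about it with
#' population-specific drift F. Inside the introgressed tract, population
#' A's frequency becomes the mixture (1 - m) A + m C.
#'
#' @param nSites Number of variants.
#' @param drift Named vector of Balding-Nichols F for populations
#'   `A`, `B`, `C`, `O`, each in (0, 1).
#' @param nPerPop Named diploid sample sizes per population.
#' @param tract Integer c(start, end) 1-based site bounds of the
#'   introgressed tract (NULL for none).
#' @param admixture Mixture fraction m in [0, 1].
#' @param ancestralShape Beta shape parameters of the ancestral frequency.
#' @param seed RNG seed.
#' @export
threePopSimConfig <- function(nSites = 5000L,
                              drift = c(A = 0.05, B = 0.05, C = 0.25, O = 0.5),
                              nPerPop = c(A = 50L, B = 50L, C = 50L, O = 20L),
                              tract = NULL, admixture = 0,
                              ancestralShape = c(0.8, 0.8), seed = 1L) {
  stopifnot(all(c("A", "B", "C", "O") %in% names(drift)),
            all(c("A", "B", "C", "O") %in% names(nPerPop)))
  if (any(drift <= 0 | drift >= 1)) stop("drift parameters must be in (0, 1)")
  if (!is.null(tract)) {
    if (tract[1] < 1L || tract[2] > nSites || tract[1] > tract[2])
      stop("tract bounds must lie within the site range")
  }
  if (admixture < 0 || admixture > 1) stop("admixture fraction must be in [0, 1]")
  structure(list(nSites = as.integer(nSites), drift = drift,
                 nPerPop = nPerPop, tract = tract, admixture = admixture,
                 ancestralShape = ancestralShape, seed = as.integer(seed)),
            class = "threePopSimConfig")
}

#' Simulate per-population allele counts with an optional introgressed tract
#'
#' @param config A [threePopSimConfig()].
#' @return List with `counts` (named list of (ref, alt) matrices for
#'   populations A, B, C, O) and `truth` (per-site data.frame of latent
#'   frequencies and the tract flag).
#' @export
simulateThreePop <- function(config) {
  stopifnot(inherits(config, "threePopSimConfig"))
  withLocalSeed(config$seed, {
    ns <- config$nSites
    panc <- rbeta(ns, config$ancestralShape[1], config$ancestralShape[2])
    panc <- pmin(pmax(panc, 0.01), 0.99)
    bn <- function(F) rbeta(ns, panc * (1 - F) / F, (1 - panc) * (1 - F) / F)
    p <- lapply(config$drift[c("A", "B", "C", "O")], bn)
    names(p) <- c("A", "B", "C", "O")
    inTract <- rep(FALSE, ns)
    if (!is.null(config$tract) && config$admixture > 0) {
      inTract[config$tract[1]:config$tract[2]] <- TRUE
      p$A[inTract] <- (1 - config$admixture) * p$A[inTract] +
        config$admixture * p$C[inTract]
    }
    counts <- lapply(c("A", "B", "C", "O"), function(g) {
      m <- 2L * config$nPerPop[[g]]
      alt <- rbinom(ns, m, p[[g]])
      cbind(ref = m - alt, alt = alt)
    })
    names(counts) <- c("A", "B", "C", "O")
    list(counts = counts,
         truth = data.frame(site = seq_len(ns), p_anc = panc,
                            p_A = p$A, p_B = p$B, p_C = p$C, p_O = p$O,
                            in_tract = inTract))
  })
}

#' Emit error-free reads with or without a duplication-junction allele
#'
#' Tiles reads of `readLength` at uniform random offsets to the requested
#' depth. Carrier samples draw reads from both the reference locus and the
#' alternative (junction-containing) sequence, so junction-spanning k-mers
#' occur only in carriers; non-carriers draw from the reference alone.
#'
#' @param samples data.frame with `sample_id` and logical `carrier`.
#' @param refSeq,altSeq Reference and alternative locus sequences
#'   (single character strings).
#' @param readLength Read length in bp (a warning is issued if below
#'   `warnK`, the downstream k-mer size).
#' @param depth Mean per-base coverage; `0` gives an empty read set.
#' @param seed RNG seed.
#' @param outDir Optional directory: one `<sample_id>.fasta` per sample.
#' @param warnK Downstream k-mer length for the read-length warning.
#' @return Named list of character read vectors, invisibly also written
#'   to `outDir` when given.
#' @export
emitReads <- function(samples, refSeq, altSeq, readLength = 100L,
                      depth = 10, seed = 1L, outDir = NULL, warnK = 31L) {
  stopifnot(all(c("sample_id", "carrier") %in% names(samples)))
  if (readLength <= warnK)
    warning("read length <= downstream k: junction k-mers may be lost")
  withLocalSeed(seed, {
    tile <- function(seqs) {
      reads <- character(0)
      for (s in seqs) {
        L <- nchar(s)
        nReads <- round(depth * L / readLength / length(seqs))
        if (nReads < 1 || L < readLength) next
        off <- sample.int(L - readLength + 1L, nReads, replace = TRUE)
        reads <- c(reads, substring(s, off, off + readLength - 1L))
      }
      reads
    }
    out <- lapply(seq_len(nrow(samples)), function(i) {
      if (depth <= 0) return(character(0))
      if (samples$carrier[i]) tile(c(refSeq, altSeq)) else tile(refSeq)
    })
    names(out) <- samples$sample_id
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      for (id in names(out)) {
        r <- out[[id]]
        writeFastaRecords(
          if (length(r)) stats::setNames(r, paste0(id, "_r", seq_along(r)))
          else character(0),
          file.path(outDir, paste0(id, ".fasta")))
      }
    }
    out
  })
}

#' Generate a random A/C/G/T sequence
#'
#' @param length Sequence length.
#' @param seed RNG seed.
#' @return Single character string.
#' @export
randomSequence <- function(length, seed = 1L) {
  withLocalSeed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}
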