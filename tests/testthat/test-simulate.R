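test_that("simulators are deterministic given config + seed and leave global RNG alone", {
  cfg <- cohortSimConfig(nSamples = 30, seed = 99)
  set.seed(1); before <- runif(1)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  set.seed(1)
  expect_identical(runif(1), before)  # caller RNG state untouched

  hm1 <- simulateSweep(sweepSimConfig(nHaplotypes = 20, nVariants = 40, seed = 5))
  hm2 <- simulateSweep(sweepSimConfig(nHaplotypes = 20, nVariants = 40, seed = 5))
  expect_identical(haplotypes(hm1), haplotypes(hm2))

  tp1 <- simulateThreePop(threePopSimConfig(nSites = 200, seed = 2))
  tp2 <- simulateThreePop(threePopSimConfig(nSites = 200, seed = 2))
  expect_identical(tp1$counts, tp2$counts)
})

test_that("cohort structure: 0 <= S <= C, binomial read fractions, logistic survival", {
  sim <- simulateCohort(cohortSimConfig(nSamples = 400, seed = 17))
  tr <- sim$truth
  expect_true(all(tr$S >= 0 & tr$S <= tr$C))
  expect_true(all(tr$C >= 2))

  ## beta_S = 0: survival rate independent of S
  sim0 <- simulateCohort(cohortSimConfig(nSamples = 4000, betaS = 0, seed = 23))
  byS <- tapply(sim0$truth$phenotype, sim0$truth$S, mean)
  expect_lt(max(byS[c("0", "1", "2")]) - min(byS[c("0", "1", "2")]), 0.06)

  ## depth large: alt fraction converges to S/C
  simD <- simulateCohort(cohortSimConfig(nSamples = 200, depthMean = 5000, seed = 2))
  calls <- cnvGenotype(simD$genotypes, simD$copyNumbers, 3500000)
  expect_lt(max(abs(calls$alt_fraction - simD$truth$S / simD$truth$C)), 0.05)
  expect_equal(calls$S, simD$truth$S)

  expect_error(cohortSimConfig(copyNumberProbs = c("1" = 1)), "C_max")
  expect_error(cohortSimConfig(copyNumberProbs = c("2" = 0.4, "3" = 0.4)), "sum to 1")
})

test_that("sweep simulator produces the prescribed degenerate and swept structure", {
  ## no recombination, no mutation: all swept haplotypes identical
  hm <- simulateSweep(sweepSimConfig(nHaplotypes = 30, nVariants = 50,
                                     recombScale = 0, mutationProb = 0, seed = 7))
  swept <- which(attr(hm, "swept"))
  h <- haplotypes(hm)
  expect_true(all(apply(h[, swept], 1, function(r) length(unique(r)) == 1)))

  ## swept frequency 1: zero haplotype diversity everywhere
  hm1 <- simulateSweep(sweepSimConfig(nHaplotypes = 20, nVariants = 50,
                                      sweptFreq = 1, recombScale = 0,
                                      mutationProb = 0, seed = 3))
  expect_equal(haplotypeDiversity(haplotypes(hm1)), 0)

  ## H12 at the focal window exceeds a frequency-matched neutral simulation
  win <- function(hm) haplotypes(hm)[51:150, , drop = FALSE]
  cmp <- vapply(1:100, function(s) {
    sw <- simulateSweep(sweepSimConfig(nHaplotypes = 100, nVariants = 200, seed = s))
    ne <- simulateSweep(sweepSimConfig(nHaplotypes = 100, nVariants = 200,
                                       recombScale = 1, seed = s))
    garudH(win(sw))$h12 > garudH(win(ne))$h12
  }, logical(1))
  expect_gte(mean(cmp), 0.95)
})

test_that("three-population simulator: null D near zero, tract D elevated, label swap flips sign", {
  ds <- vapply(1:60, function(s) {
    tp <- simulateThreePop(threePopSimConfig(nSites = 1000, seed = s))
    regionDWithJackknife(tp$counts$A, tp$counts$B, tp$counts$C, tp$counts$O,
                         blockLength = 100L)$d
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.02)

  inOut <- vapply(1:60, function(s) {
    tp <- simulateThreePop(threePopSimConfig(
      nSites = 2000, drift = c(A = 0.05, B = 0.05, C = 0.4, O = 0.5),
      tract = c(501, 1500), admixture = 1, seed = s))
    dIn <- regionDWithJackknife(tp$counts$A, tp$counts$B, tp$counts$C,
                                tp$counts$O, region = c(501, 1500))$d
    cOut <- lapply(tp$counts, function(m) m[c(1:500, 1501:2000), ])
    dOut <- regionDWithJackknife(cOut$A, cOut$B, cOut$C, cOut$O)$d
    ## introgression from C into A drives D negative: compare magnitudes
    abs(dIn) > abs(dOut)
  }, logical(1))
  expect_gte(mean(inOut), 0.95)

  tp <- simulateThreePop(threePopSimConfig(nSites = 500, tract = c(101, 400),
                                           admixture = 0.5, seed = 9))
  dAB <- regionDWithJackknife(tp$counts$A, tp$counts$B, tp$counts$C, tp$counts$O)$d
  dBA <- regionDWithJackknife(tp$counts$B, tp$counts$A, tp$counts$C, tp$counts$O)$d
  expect_equal(dAB, -dBA, tolerance = 1e-12)

  expect_error(threePopSimConfig(tract = c(0, 10)), "tract")
  expect_error(threePopSimConfig(drift = c(A = 0, B = 0.1, C = 0.1, O = 0.1)),
               "drift")
})

test_that("read emission tiles carriers with junction sequence and respects depth", {
  ref <- randomSequence(800, seed = 5)
  alt <- paste0(substr(ref, 1, 400), randomSequence(60, seed = 6),
                substr(ref, 401, 800))
  samples <- data.frame(sample_id = c("car", "non"), carrier = c(TRUE, FALSE))
  reads <- emitReads(samples, ref, alt, readLength = 100L, depth = 8,
                     seed = 21)
  expect_gt(length(reads$car), 0)
  expect_gt(length(reads$non), 0)
  ## non-carrier reads are all substrings of the reference
  expect_true(all(vapply(reads$non, function(r) grepl(r, ref, fixed = TRUE),
                         logical(1))))
  ## junction-spanning k-mers occur only in the carrier
  junctionKmers <- substring(alt, 371:430, 401:460)
  tab <- countKmers(list(car = reads$car, non = reads$non), k = 31L)
  codes <- kmerEncode(junctionKmers[nchar(junctionKmers) == 31])
  hits <- match(codes, tab@codes)
  expect_true(all(tab@counts[hits[!is.na(hits)], "non"] == 0))

  ## depth 0: empty read set, zero k-mers for that sample
  r0 <- emitReads(samples, ref, alt, depth = 0, seed = 1)
  expect_length(r0$car, 0L)

  ## single read covering the whole sequence reproduces its k-mer counts
  one <- emitReads(data.frame(sample_id = "s", carrier = FALSE),
                   ref, alt, readLength = 800L, depth = 1, seed = 2)
  direct <- countKmers(list(s = ref), k = 15L)
  viaReads <- countKmers(list(s = one$s), k = 15L)
  expect_equal(viaReads@codes, direct@codes)
  expect_equal(viaReads@counts, direct@counts)
})

test_that("generated VCF/TSV outputs pass strict io validation", {
  sim <- simulateCohort(cohortSimConfig(nSamples = 25, seed = 13))
  d <- withr::local_tempdir()
  writeGenotypeVcf(sim$genotypes, file.path(d, "c.vcf"))
  writeTsv(sim$phenotypes, file.path(d, "p.tsv"))
  writeTsv(sim$copyNumbers, file.path(d, "cn.tsv"))
  expect_s4_class(readGenotypeVcf(file.path(d, "c.vcf")), "GenotypeMatrix")
  expect_equal(readPhenotypes(file.path(d, "p.tsv"))$phenotype,
               sim$phenotypes$phenotype)
  expect_equal(readCopyNumbers(file.path(d, "cn.tsv"))$copy_number,
               sim$copyNumbers$copy_number)
})
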