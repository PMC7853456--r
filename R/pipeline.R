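## Orchestration of the two headline workflows: genotype-phenotype
## association at the focal SNP, and locus characterisation (sweep
## profiles, haplotype network, EHH, introgression). Reports are plain
## lists of data.frames; writers emit TSV so plotting stays decoupled.

#' Pipeline configuration
#'
#' @param vcf,copies,phenotypes Input file paths (VCF with GT/AD;
#'   copy-number TSV; phenotype TSV).
#' @param focalSite 1-based position of the resistance SNP.
#' @param breakpoints Integer c(start, end), 1-based inclusive duplication
#'   interval.
#' @param windowSize,overlap,fdrThreshold Stage parameters.
#' @param seed Seed recorded in every report.
#' @param validateFiles Check that the referenced files exist.
#' @return Config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(vcf = NULL, copies = NULL, phenotypes = NULL,
                           focalSite = NULL, breakpoints = NULL,
                           windowSize = 1000L, overlap = 0.2,
                           fdrThreshold = 0.001, seed = 1L,
                           validateFiles = TRUE) {
  if (!is.null(breakpoints) && breakpoints[1] >= breakpoints[2])
    stop("breakpoint start must precede end")
  if (validateFiles) {
    for (f in c(vcf, copies, phenotypes))
      if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  structure(list(vcf = vcf, copies = copies, phenotypes = phenotypes,
                 focalSite = focalSite, breakpoints = breakpoints,
                 windowSize = windowSize, overlap = overlap,
                 fdrThreshold = fdrThreshold, seed = seed),
            class = "pipelineConfig")
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file with the fields of [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

#' Genotype-phenotype association workflow
#'
#' Chains copy-number-aware genotyping of the focal site into the
#' association battery: per-genotype survival tables, Fisher exact test
#' and Woolf odds ratio for resistance-allele carriage, binomial GLMs on
#' C and S, the BIC-minimal model, and the confusion matrix of the
#' dosage-based resistance classification. Samples missing a phenotype
#' are listed and excluded; the run continues.
#'
#' @param config A [pipelineConfig()] (file paths), or pass the objects
#'   directly.
#' @param gm,copyNumbers,phenotypes Optional in-memory inputs overriding
#'   the config paths.
#' @return Report list with elements `s_calls`, `survival_by_genotype`,
#'   `carrier_test`, `glm_C`, `glm_S`, `stepwise`, `confusion`,
#'   `excluded_samples`, `config`, `version`.
#' @export
runAssociationWorkflow <- function(config, gm = NULL, copyNumbers = NULL,
                                   phenotypes = NULL) {
  if (is.null(gm)) gm <- readGenotypeVcf(config$vcf)
  if (is.null(copyNumbers)) copyNumbers <- readCopyNumbers(config$copies)
  if (is.null(phenotypes)) phenotypes <- readPhenotypes(config$phenotypes)
  calls <- cnvGenotype(gm, copyNumbers, config$focalSite)
  idx <- match(calls$sample_id, phenotypes$sample_id)
  excluded <- calls$sample_id[is.na(idx)]
  keep <- !is.na(idx)
  calls <- calls[keep, , drop = FALSE]
  y <- phenotypes$phenotype[idx[keep]]
  surv <- do.call(rbind, lapply(split(seq_along(y), calls$S), function(i)
    data.frame(S = calls$S[i[1]], n = length(i), alive = sum(y[i]),
               survival = mean(y[i]))))
  carrier <- factor(calls$S > 0, levels = c(TRUE, FALSE))
  tab <- table(carrier, factor(y, levels = c(1, 0)))
  wo <- woolfOr(tab)
  fitC <- fitBinomialGlm(y, data.frame(C = calls$C))
  fitS <- fitBinomialGlm(y, data.frame(S = calls$S))
  sw <- stepwiseBic(y, data.frame(C = calls$C, S = calls$S))
  conf <- table(predicted = calls$predicted_class,
                observed = ifelse(y == 1, "resistant", "susceptible"))
  list(
    s_calls = calls,
    survival_by_genotype = surv,
    carrier_test = list(table = tab, fisher_p = fisherExact(tab),
                        or = wo$or, ci = c(wo$ci_low, wo$ci_high)),
    glm_C = fitC, glm_S = fitS,
    stepwise = sw,
    confusion = conf,
    excluded_samples = excluded,
    config = config,
    version = as.character(utils::packageVersion("dupsweep")),
    seed = config$seed
  )
}

#' Locus characterisation workflow
#'
#' On a phased haplotype set spanning a duplication: profiles Garud's H
#' statistics and haplotype diversity for carrier and background
#' haplotypes of a focal allele, builds the identical-haplotype network
#' around the focal variant, computes EHH decay outward from it, and — when
#' three-population allele counts are supplied — the windowed Patterson's D
#' with block-jackknife significance and three-population branch lengths.
#'
#' @param hm A [HaplotypeMatrix-class].
#' @param focalIndex 1-based focal variant row.
#' @param windowSize,overlap Sweep-profile windows.
#' @param counts Optional named list (A, B, C, O) of allele-count matrices
#'   for the introgression stage.
#' @param blockLength Jackknife block length (variants).
#' @param seed Seed recorded in the report.
#' @return Report list with `network`, `profile_carrier`,
#'   `profile_background`, `ehh`, and optionally `d_test`,
#'   `branch_lengths`.
#' @export
runLocusCharacterisation <- function(hm, focalIndex, windowSize = 100L,
                                     overlap = 0.2, counts = NULL,
                                     blockLength = 100L, seed = 1L) {
  stopifnot(is(hm, "HaplotypeMatrix"))
  h <- haplotypes(hm)
  carrier <- h[focalIndex, ] == 1L
  if (!any(carrier) || all(carrier))
    stop("focal allele must segregate among the haplotypes")
  net <- buildHaplotypeNetwork(hm, tagAlleles = h[focalIndex, ])
  win <- min(windowSize, nrow(h))
  profC <- sweepProfile(hm[, which(carrier)], win, overlap)
  profB <- sweepProfile(hm[, which(!carrier)], win, overlap)
  ehhC <- ehhDecay(h[, carrier, drop = FALSE], focalIndex, "down")
  ehhB <- ehhDecay(h[, !carrier, drop = FALSE], focalIndex, "down")
  rep <- list(network = net, profile_carrier = profC,
              profile_background = profB,
              ehh = list(carrier = ehhC, background = ehhB),
              version = as.character(utils::packageVersion("dupsweep")),
              seed = seed)
  if (!is.null(counts)) {
    rep$d_test <- regionDWithJackknife(counts$A, counts$B, counts$C,
                                       counts$O, blockLength = blockLength)
    rep$branch_lengths <- threePopBranchLengths(counts$A, counts$B, counts$C,
                                                windowSize = blockLength,
                                                labels = c("A", "B", "C"))
  }
  rep
}

#' Write an association report as TSV files
#'
#' @param report From [runAssociationWorkflow()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeAssociationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(report$s_calls, file.path(dir, "s_calls.tsv"))
  writeTsv(report$survival_by_genotype, file.path(dir, "survival_by_genotype.tsv"))
  writeTsv(report$stepwise$coefficients, file.path(dir, "minimal_model.tsv"))
  ct <- report$carrier_test
  writeTsv(data.frame(test = "carrier_vs_wt", fisher_p = ct$fisher_p,
                      odds_ratio = ct$or, ci_low = ct$ci[1], ci_high = ct$ci[2]),
           file.path(dir, "carrier_test.tsv"))
  invisible(dir)
}
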