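## Copy-number-aware dosage of the resistance allele. A sample with C locus
## copies and an alternate-read fraction f is assigned the integer S in
## 0..C whose expected fraction S/C lies closest to f; ties go to the
## smaller S (conservative toward wild type).

#' Alternate-allele read fraction
#'
#' @param refReads,altReads Non-negative read counts supporting the
#'   reference and alternate allele.
#' @return `altReads / (refReads + altReads)`. Zero total depth is an
#'   error, never silently 0 — a sample without coverage carries no dosage
#'   information.
#' @export
altFraction <- function(refReads, altReads) {
  stopifnot(all(refReads >= 0), all(altReads >= 0))
  tot <- refReads + altReads
  if (any(tot == 0)) stop("no depth: ref and alt read counts are both zero")
  altReads / tot
}

#' Estimate resistant-allele copies from copy number and read fraction
#'
#' Given locus copy number `C` and the fraction of reads supporting the
#' resistance allele, returns the integer dosage S minimising
#' `|altFraction - S/C|` over S in 0..C. For example C = 3 with 30% of
#' reads supporting the alternate allele gives S = 1 (S/C = 1/3).
#'
#' @param C Integer locus copy number, >= 1 (vectorised).
#' @param altFraction Read fraction in [0, 1] (vectorised).
#' @return Integer vector of resistant-allele copy estimates.
#' @export
estimateResistantCopies <- function(C, altFraction) {
  C <- as.integer(C)
  if (any(C < 1L)) stop("locus copy number must be >= 1")
  if (any(altFraction < 0 | altFraction > 1)) stop("altFraction must be in [0, 1]")
  n <- max(length(C), length(altFraction))
  C <- rep_len(C, n); f <- rep_len(altFraction, n)
  vapply(seq_len(n), function(i) {
    s <- 0:C[i]
    ## which.min takes the first minimiser: ties break toward smaller S
    s[which.min(abs(f[i] - s / C[i]))]
  }, integer(1))
}

#' Classify a duplication configuration
#'
#' Maps (C, S) to one of `WT_SINGLE` (no duplication, no resistant allele),
#' `HET_DUP` (duplication carrying both wild-type and resistant copies),
#' `HOM_DUP_ALT` (duplication with only resistant copies) or `HOM_DUP_WT`
#' (duplication with only wild-type copies). Non-duplicated carriers
#' (C <= 2, S > 0) are reported as `SNP_ONLY`.
#'
#' @param C Locus copies (>= 1).
#' @param S Resistant copies, 0 <= S <= C.
#' @return Character vector of configuration labels.
#' @export
classifyConfiguration <- function(C, S) {
  n <- max(length(C), length(S))
  C <- rep_len(as.integer(C), n); S <- rep_len(as.integer(S), n)
  if (any(S > C)) stop("S may not exceed C")
  if (any(S < 0L) || any(C < 1L)) stop("require C >= 1 and S >= 0")
  out <- character(n)
  out[C <= 2L & S == 0L] <- "WT_SINGLE"
  out[C <= 2L & S > 0L] <- "SNP_ONLY"
  out[C > 2L & S == 0L] <- "HOM_DUP_WT"
  out[C > 2L & S == C] <- "HOM_DUP_ALT"
  out[C > 2L & S > 0L & S < C] <- "HET_DUP"
  out
}

#' Predict resistance class from allele dosage
#'
#' Classification rule: a sample with more wild-type than resistant copies
#' (or none resistant) is called susceptible; one with at least as many
#' resistant as wild-type copies (and at least one) is called resistant.
#'
#' @inheritParams classifyConfiguration
#' @return Character vector, `"resistant"` or `"susceptible"`.
#' @export
predictResistance <- function(C, S) {
  n <- max(length(C), length(S))
  C <- rep_len(as.integer(C), n); S <- rep_len(as.integer(S), n)
  if (any(S > C)) stop("S may not exceed C")
  ifelse(S > 0L & S >= C - S, "resistant", "susceptible")
}

#' Copy-number-aware genotyping of a focal site across a cohort
#'
#' Combines a genotype matrix with AD depths (or a precomputed fraction
#' table) and a per-sample copy-number table into per-sample records of
#' (C, alt fraction, S, configuration, predicted class).
#'
#' @param gm A [GenotypeMatrix-class] carrying allele depths.
#' @param copyNumbers data.frame from [readCopyNumbers()].
#' @param site 1-based position of the focal resistance SNP.
#' @return data.frame with columns `sample_id`, `C`, `ref_reads`,
#'   `alt_reads`, `alt_fraction`, `S`, `configuration`, `predicted_class`.
#' @export
cnvGenotype <- function(gm, copyNumbers, site) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!hasDepths(gm))
    stop("no depth: genotype matrix carries no AD field, cannot estimate S")
  i <- match(as.integer(site), positions(gm))
  if (is.na(i)) stop("focal site ", site, " not present in genotype matrix")
  idx <- match(sampleIds(gm), copyNumbers$sample_id)
  if (any(is.na(idx)))
    stop("missing copy number for sample(s): ",
         paste(sampleIds(gm)[is.na(idx)], collapse = ", "))
  C <- copyNumbers$copy_number[idx]
  refR <- gm@refDepth[i, ]
  altR <- gm@altDepth[i, ]
  if (any(is.na(refR) | is.na(altR)) || any(refR + altR == 0))
    stop("no depth at focal site for one or more samples")
  f <- altFraction(refR, altR)
  S <- estimateResistantCopies(C, f)
  data.frame(
    sample_id = sampleIds(gm), C = C,
    ref_reads = refR, alt_reads = altR,
    alt_fraction = f, S = S,
    configuration = classifyConfiguration(C, S),
    predicted_class = predictResistance(C, S),
    stringsAsFactors = FALSE
  )
}
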