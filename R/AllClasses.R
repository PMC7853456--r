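## Central S4 containers. Genotypes are stored as two integer allele-code
## matrices (variant x sample) rather than a 3-d array so that column/row
## subsetting stays cheap; -1L marks a missing allele call.

#' GenotypeMatrix: biallelic variant-by-sample genotype calls
#'
#' Holds diploid genotype calls for biallelic variants on one contig, with
#' optional per-sample ref/alt read depths (VCF AD field). Allele codes are
#' 0 (reference), 1 (alternate) and -1 (missing); both alleles of a call are
#' missing together.
#'
#' @slot chrom Single contig label.
#' @slot positions Integer vector of 1-based variant positions, strictly
#'   increasing.
#' @slot allele1,allele2 Integer matrices (variant x sample) of allele codes.
#' @slot refDepth,altDepth Integer matrices of supporting read counts, or
#'   0 x 0 matrices when the source carried no AD field.
#' @slot sampleIds Character vector of unique sample labels.
#'
#' @export
setClass("GenotypeMatrix",
  representation(
    chrom = "character",
    positions = "integer",
    allele1 = "matrix",
    allele2 = "matrix",
    refDepth = "matrix",
    altDepth = "matrix",
    sampleIds = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  nv <- length(object@positions)
  ns <- length(object@sampleIds)
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be a single label")
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "sample ids must be unique")
  if (nv > 1L && any(diff(object@positions) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  for (s in c("allele1", "allele2")) {
    m <- slot(object, s)
    if (!all(dim(m) == c(nv, ns)))
      msg <- c(msg, sprintf("%s must be %d x %d", s, nv, ns))
    if (length(m) && !all(m %in% c(-1L, 0L, 1L)))
      msg <- c(msg, sprintf("%s codes must be in {-1, 0, 1}", s))
  }
  if (hasDepths(object)) {
    for (s in c("refDepth", "altDepth")) {
      m <- slot(object, s)
      if (!all(dim(m) == c(nv, ns)))
        msg <- c(msg, sprintf("%s must be %d x %d", s, nv, ns))
      if (length(m) && any(m < 0L, na.rm = TRUE))
        msg <- c(msg, sprintf("%s must be non-negative", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param chrom Contig label.
#' @param positions 1-based positions (coerced to integer).
#' @param allele1,allele2 Variant x sample integer matrices of allele codes
#'   in \{-1, 0, 1\}.
#' @param refDepth,altDepth Optional matching matrices of read counts; leave
#'   `NULL` when the source has no depth information (downstream dosage
#'   estimation then refuses to run rather than assuming zero coverage).
#' @param sampleIds Unique sample labels.
#' @return A validated [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(chrom, positions, allele1, allele2,
                           refDepth = NULL, altDepth = NULL, sampleIds) {
  empty <- matrix(integer(), 0L, 0L)
  new("GenotypeMatrix",
    chrom = as.character(chrom),
    positions = as.integer(positions),
    allele1 = matrix(as.integer(allele1), nrow(allele1), ncol(allele1)),
    allele2 = matrix(as.integer(allele2), nrow(allele2), ncol(allele2)),
    refDepth = if (is.null(refDepth)) empty else
      matrix(as.integer(refDepth), nrow(refDepth), ncol(refDepth)),
    altDepth = if (is.null(altDepth)) empty else
      matrix(as.integer(altDepth), nrow(altDepth), ncol(altDepth)),
    sampleIds = as.character(sampleIds)
  )
}

#' HaplotypeMatrix: phased binary variant-by-haplotype alleles
#'
#' @slot chrom Contig label.
#' @slot positions 1-based variant positions, strictly increasing.
#' @slot haplotypes Integer matrix (variant x haplotype) with entries in
#'   \{0, 1\}.
#' @slot haplotypeIds Character labels, conventionally `"<sample>_1"` /
#'   `"<sample>_2"` for the two phases of a diploid sample.
#' @export
setClass("HaplotypeMatrix",
  representation(
    chrom = "character",
    positions = "integer",
    haplotypes = "matrix",
    haplotypeIds = "character"
  )
)

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be a single label")
  nv <- length(object@positions)
  if (nrow(object@haplotypes) != nv)
    msg <- c(msg, "haplotypes rows must match positions")
  if (ncol(object@haplotypes) != length(object@haplotypeIds))
    msg <- c(msg, "haplotype ids must match haplotype columns")
  if (nv > 1L && any(diff(object@positions) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@haplotypes) && !all(object@haplotypes %in% c(0L, 1L)))
    msg <- c(msg, "haplotype alleles must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeMatrix
#'
#' @param chrom Contig label.
#' @param positions 1-based variant positions.
#' @param haplotypes Variant x haplotype 0/1 matrix.
#' @param haplotypeIds Haplotype labels; defaults to `h1..hN`.
#' @return A validated [HaplotypeMatrix-class] object.
#' @export
HaplotypeMatrix <- function(chrom, positions, haplotypes,
                            haplotypeIds = paste0("h", seq_len(ncol(haplotypes)))) {
  new("HaplotypeMatrix",
    chrom = as.character(chrom),
    positions = as.integer(positions),
    haplotypes = matrix(as.integer(haplotypes), nrow(haplotypes), ncol(haplotypes)),
    haplotypeIds = as.character(haplotypeIds)
  )
}

#' KmerTable: canonical k-mer counts across samples
#'
#' Counts of canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) per sample. Codes are the 2-bit packing of the
#' canonical sequence (A=0, C=1, G=2, T=3), carried as decimal strings so
#' that 62-bit codes (k = 31) stay exact.
#'
#' @slot k K-mer length (odd, at most 31).
#' @slot codes Character vector of decimal 2-bit-packed canonical codes.
#' @slot counts Integer matrix (k-mer x sample).
#' @slot retained Logical per-k-mer flag set by [filterVariantKmers()].
#' @slot sampleTotals Numeric per-sample normalisation totals (sums of
#'   retained counts); `NA` before filtering.
#' @slot shortReads Integer tally of reads shorter than k skipped per sample.
#' @export
setClass("KmerTable",
  representation(
    k = "integer",
    codes = "character",
    counts = "matrix",
    retained = "logical",
    sampleTotals = "numeric",
    shortReads = "integer"
  )
)

setValidity("KmerTable", function(object) {
  msg <- character()
  if (object@k < 1L || object@k > 31L || object@k %% 2L == 0L)
    msg <- c(msg, "k must be odd and at most 31")
  if (nrow(object@counts) != length(object@codes))
    msg <- c(msg, "counts rows must match codes")
  if (length(object@retained) != length(object@codes))
    msg <- c(msg, "retained flags must match codes")
  if (length(object@counts) && any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (anyDuplicated(object@codes)) msg <- c(msg, "codes must be unique")
  if (length(msg)) msg else TRUE
})

## ---- generics and accessors ------------------------------------------------

#' @rdname GenotypeMatrix-class
#' @param x,object A container object.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("hasDepths", function(x) standardGeneric("hasDepths"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))

setMethod("nVariants", "GenotypeMatrix", function(x) length(x@positions))
setMethod("nSamples", "GenotypeMatrix", function(x) length(x@sampleIds))
setMethod("positions", "GenotypeMatrix", function(x) x@positions)
setMethod("chrom", "GenotypeMatrix", function(x) x@chrom)
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleIds)
setMethod("hasDepths", "GenotypeMatrix", function(x) length(x@refDepth) > 0L)

#' @describeIn GenotypeMatrix-class Alternate-allele dosage matrix
#'   (variant x sample) with `NA` at missing calls.
setMethod("dosages", "GenotypeMatrix", function(x) {
  a1 <- x@allele1
  a2 <- x@allele2
  d <- a1 + a2
  d[a1 < 0L | a2 < 0L] <- NA_integer_
  dimnames(d) <- list(NULL, x@sampleIds)
  d
})

setMethod("nVariants", "HaplotypeMatrix", function(x) length(x@positions))
setMethod("nSamples", "HaplotypeMatrix", function(x) ncol(x@haplotypes) %/% 2L)
setMethod("positions", "HaplotypeMatrix", function(x) x@positions)
setMethod("chrom", "HaplotypeMatrix", function(x) x@chrom)
setMethod("haplotypes", "HaplotypeMatrix", function(x) x@haplotypes)
setMethod("haplotypeIds", "HaplotypeMatrix", function(x) x@haplotypeIds)

#' Extract read-depth matrices
#'
#' @param x A [GenotypeMatrix-class].
#' @return A list with `ref` and `alt` integer matrices, or `NULL` when the
#'   source carried no AD field.
#' @export
alleleDepths <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (!hasDepths(x)) return(NULL)
  list(ref = x@refDepth, alt = x@altDepth)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix: %d biallelic variants x %d samples on %s (%sAD)\n",
    nVariants(object), nSamples(object), object@chrom,
    if (hasDepths(object)) "with " else "no "
  ))
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("HaplotypeMatrix: %d variants x %d haplotypes on %s\n",
    nVariants(object), ncol(object@haplotypes), object@chrom))
})

setMethod("show", "KmerTable", function(object) {
  cat(sprintf("KmerTable: %d canonical %d-mers x %d samples (%d retained)\n",
    length(object@codes), object@k, ncol(object@counts),
    sum(object@retained)))
})

#' Subset a GenotypeMatrix by variant index and/or sample
#'
#' @param x A [GenotypeMatrix-class].
#' @param i Variant indices (logical or integer).
#' @param j Sample indices, names, or logical.
#' @param ... Ignored.
#' @param drop Ignored; the class is always returned.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@positions)
  if (missing(j)) j <- seq_along(x@sampleIds)
  if (is.character(j)) j <- match(j, x@sampleIds)
  dep <- hasDepths(x)
  GenotypeMatrix(
    chrom = x@chrom,
    positions = x@positions[i],
    allele1 = x@allele1[i, j, drop = FALSE],
    allele2 = x@allele2[i, j, drop = FALSE],
    refDepth = if (dep) x@refDepth[i, j, drop = FALSE] else NULL,
    altDepth = if (dep) x@altDepth[i, j, drop = FALSE] else NULL,
    sampleIds = x@sampleIds[j]
  )
})

#' Subset a HaplotypeMatrix by variant index and/or haplotype
#'
#' @param x A [HaplotypeMatrix-class].
#' @param i Variant indices.
#' @param j Haplotype indices or labels.
#' @param ... Ignored.
#' @param drop Ignored.
#' @export
setMethod("[", "HaplotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@positions)
  if (missing(j)) j <- seq_along(x@haplotypeIds)
  if (is.character(j)) j <- match(j, x@haplotypeIds)
  HaplotypeMatrix(x@chrom, x@positions[i],
    x@haplotypes[i, j, drop = FALSE], x@haplotypeIds[j])
})

#' Per-population alternate-allele counts from genotypes
#'
#' Counts alleles over non-missing calls only, so frequency denominators
#' shrink where data are missing (sites are filtered, never imputed).
#'
#' @param gm A [GenotypeMatrix-class].
#' @param samples Optional sample subset (names or indices).
#' @return Integer matrix with columns `ref`, `alt` (one row per variant).
#' @export
alleleCounts <- function(gm, samples = NULL) {
  stopifnot(is(gm, "GenotypeMatrix"))
  x <- if (is.null(samples)) gm else gm[, samples]
  a1 <- x@allele1
  a2 <- x@allele2
  alt <- rowSums((a1 == 1L) + (a2 == 1L))
  ref <- rowSums((a1 == 0L) + (a2 == 0L))
  cbind(ref = as.integer(ref), alt = as.integer(alt))
}
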