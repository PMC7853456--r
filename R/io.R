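## External formats. Coordinates are 1-based inclusive on disk (VCF
## convention); window arithmetic elsewhere uses 0-based half-open variant
## indices. Writers emit UTF-8 TSV with '.' for missing.

#' Read a VCF into a GenotypeMatrix
#'
#' Parses GT (required) and AD (optional) from a VCF 4.x file. Only
#' biallelic SNV records are representable; multiallelic records are an
#' error under `strict = TRUE` (the default) and are dropped with a warning
#' otherwise. Genotypes `./.` become missing (-1) calls. When the file has
#' no AD field the result carries no depth matrices at all — downstream
#' dosage estimation then signals "no depth" instead of treating coverage
#' as zero.
#'
#' @param path VCF file path (plain text or bgzip).
#' @param strict Reject multiallelic records instead of dropping them.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeVcf <- function(path, strict = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix[, "ALT"]) | fix[, "ALT"] %in% c(".", "")
  if (any(multi)) {
    if (strict) {
      stop("non-biallelic record(s) at ", fix[which(multi)[1L], "CHROM"], ":",
           fix[which(multi)[1L], "POS"], " (strict mode)")
    }
    warning(sum(multi), " non-biallelic record(s) dropped")
  }
  keep <- !multi
  chroms <- unique(fix[keep, "CHROM"])
  if (length(chroms) != 1L)
    stop("expected a single contig per file, found: ", paste(chroms, collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  sep <- gsub("[^/|]", "", gt[!is.na(gt)][1])
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  code <- function(a) {
    out <- suppressWarnings(matrix(as.integer(a), nrow(gt), ncol(gt)))
    out[a == "." | is.na(a)] <- -1L
    out
  }
  a1 <- code(a1); a2 <- code(a2)
  bad <- a1 > 1L | a2 > 1L
  if (any(bad, na.rm = TRUE)) stop("allele index above 1 in GT field: not biallelic")
  ## alleles of one call are missing together
  miss <- a1 < 0L | a2 < 0L
  a1[miss] <- -1L; a2[miss] <- -1L
  refD <- altD <- NULL
  if ("AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
    if (any(!is.na(ad))) {
      refD <- suppressWarnings(matrix(as.integer(sub(",.*", "", ad)), nrow(ad), ncol(ad)))
      altD <- suppressWarnings(matrix(as.integer(sub(".*?,", "", ad)), nrow(ad), ncol(ad)))
    }
  }
  GenotypeMatrix(
    chrom = chroms, positions = as.integer(fix[keep, "POS"]),
    allele1 = a1, allele2 = a2,
    refDepth = refD, altDepth = altD, sampleIds = samples
  )
}

#' Write a GenotypeMatrix as VCF 4.2
#'
#' Emits unphased GT (plus AD when depths are present) with placeholder
#' REF/ALT alleles `A`/`T` unless supplied. `writeGenotypeVcf()` then
#' [readGenotypeVcf()] is the identity on the genotype and depth matrices.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param path Output path.
#' @param ref,alt Allele strings recycled across variants.
#' @param phased Write `|` instead of `/` separators.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(gm, path, ref = "A", alt = "T", phased = FALSE) {
  stopifnot(is(gm, "GenotypeMatrix"))
  nv <- nVariants(gm)
  ref <- rep_len(ref, nv); alt <- rep_len(alt, nv)
  sep <- if (phased) "|" else "/"
  dep <- hasDepths(gm)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom(gm)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (dep) "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(gm)), collapse = "\t")
  ), con)
  gchar <- function(m) ifelse(m < 0L, ".", as.character(m))
  gt <- matrix(paste0(gchar(gm@allele1), sep, gchar(gm@allele2)), nv)
  if (dep) {
    ad <- matrix(ifelse(is.na(gm@refDepth) | is.na(gm@altDepth), ".",
                        paste0(gm@refDepth, ",", gm@altDepth)), nv)
    gt <- matrix(paste0(gt, ":", ad), nv)
  }
  lines <- paste(chrom(gm), positions(gm), ".", ref, alt, ".", "PASS", ".",
                 if (dep) "GT:AD" else "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a HaplotypeMatrix as a phased VCF
#'
#' @inheritParams writeGenotypeVcf
#' @param hm A [HaplotypeMatrix-class] with an even number of haplotypes;
#'   consecutive pairs become one diploid sample.
#' @export
writeHaplotypeVcf <- function(hm, path, ref = "A", alt = "T") {
  stopifnot(is(hm, "HaplotypeMatrix"), ncol(hm@haplotypes) %% 2L == 0L)
  h <- hm@haplotypes
  odd <- seq(1L, ncol(h), by = 2L)
  gm <- GenotypeMatrix(chrom(hm), positions(hm),
    allele1 = h[, odd, drop = FALSE], allele2 = h[, odd + 1L, drop = FALSE],
    sampleIds = sub("_[12]$", "", hm@haplotypeIds[odd]))
  writeGenotypeVcf(gm, path, ref, alt, phased = TRUE)
}

#' Read a phased VCF into a HaplotypeMatrix
#'
#' Requires every genotype to be phased (`|`) and non-missing; each diploid
#' sample contributes haplotypes `<id>_1` and `<id>_2`.
#'
#' @param path VCF path.
#' @return A [HaplotypeMatrix-class].
#' @export
readHaplotypeVcf <- function(path) {
  gm <- readGenotypeVcf(path, strict = TRUE)
  if (any(gm@allele1 < 0L | gm@allele2 < 0L))
    stop("phased input may not contain missing genotypes")
  nh <- 2L * nSamples(gm)
  h <- matrix(0L, nVariants(gm), nh)
  h[, seq(1L, nh, 2L)] <- gm@allele1
  h[, seq(2L, nh, 2L)] <- gm@allele2
  HaplotypeMatrix(chrom(gm), positions(gm), h,
    paste0(rep(sampleIds(gm), each = 2L), "_", 1:2))
}

#' Read a binary-phenotype table
#'
#' Expects a TSV with header columns `sample_id`, `phenotype`, `population`.
#' Phenotype vocabulary: `1`/`alive`/`resistant` map to 1 and
#' `0`/`dead`/`susceptible` map to 0; anything else is an error, as is a
#' duplicated sample id.
#'
#' @param path TSV path.
#' @return A data.frame with columns `sample_id`, `phenotype` (integer 0/1),
#'   `population`.
#' @export
readPhenotypes <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("sample_id", "phenotype", "population")
  if (!all(need %in% names(d)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample id: ", d$sample_id[anyDuplicated(d$sample_id)])
  vocab <- c("1" = 1L, "alive" = 1L, "resistant" = 1L,
             "0" = 0L, "dead" = 0L, "susceptible" = 0L)
  ph <- vocab[tolower(d$phenotype)]
  if (any(is.na(ph)))
    stop("unknown phenotype value: ", d$phenotype[which(is.na(ph))[1L]])
  data.frame(sample_id = d$sample_id, phenotype = unname(ph),
             population = d$population, stringsAsFactors = FALSE)
}

#' Read a per-sample locus copy-number table
#'
#' TSV with header columns `sample_id` and `copy_number` (integer >= 1).
#'
#' @param path TSV path.
#' @return data.frame with `sample_id`, `copy_number`.
#' @export
readCopyNumbers <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("sample_id", "copy_number") %in% names(d)))
    stop("copy-number table must have columns sample_id, copy_number")
  if (anyDuplicated(d$sample_id)) stop("duplicated sample id in copy-number table")
  if (any(d$copy_number < 1L)) stop("copy numbers must be >= 1")
  data.frame(sample_id = as.character(d$sample_id),
             copy_number = as.integer(d$copy_number), stringsAsFactors = FALSE)
}

#' Read FASTA records
#'
#' @param path FASTA path.
#' @param strict Error on characters outside A/C/G/T/N.
#' @return Named character vector of uppercased sequences, in file order.
#' @export
readFastaRecords <- function(path, strict = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  if (strict && any(grepl("[^ACGTN]", seqs)))
    stop("illegal sequence character in ", path)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write FASTA records
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
writeFastaRecords <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a data.frame as a plain TSV
#'
#' Tab-delimited, UTF-8, header row, `.` for missing values.
#' @param d data.frame.
#' @param path Output path.
#' @export
writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".", fileEncoding = "UTF-8")
  invisible(path)
}
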