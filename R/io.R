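#' Read genotypes from a VCF file
#'
#' Parses diploid GT fields into alt-allele dosages. Multi-allelic
#' records and non-SNP records (indels) are skipped and the number of
#' skipped records is reported via `message()`. Phasing is ignored
#' (`0|1` and `0/1` both give dosage 1); any call containing `.` is
#' missing.
#'
#' @param path path to a VCF 4.x file with GT in FORMAT.
#' @return A [GenotypeMatrix-class].
#' @seealso [writeVCF()] for the inverse.
#' @export
readVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  nskip <- sum(!keep)
  if (nskip > 0)
    message("readVCF: skipped ", nskip, " multi-allelic or non-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  codes <- .gtToDosage(gt)        # variants x samples
  GenotypeMatrix(t(codes),
                 data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                            ref = fix$REF, alt = fix$ALT,
                            stringsAsFactors = FALSE))
}

.gtToDosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  d
}

#' Write a GenotypeMatrix as minimal VCF 4.2
#'
#' Emits biallelic SNP records with a GT-only FORMAT column; dosage 0,
#' 1, 2 become `0/0`, `0/1`, `1/1` and missing becomes `./.`.
#'
#' @param x a [GenotypeMatrix-class]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writeVCF <- function(x, path) {
  vt <- variantInfo(x)
  cd <- genoCodes(x)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nVariants(x), nSamples(x))
  ok <- !is.na(t(cd))
  gt[ok] <- gtmap[t(cd)[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleIds(x)), collapse = "\t"))
  body <- paste(vt$chrom, vt$pos, variantIds(vt), vt$ref, vt$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Genotype matrix TSV round trip
#'
#' The TSV layout is rows = samples, columns = variants (header names
#' encode `chrom:pos_ref/alt`), codes 0/1/2 and `NA` for missing.
#'
#' @param x a [GenotypeMatrix-class]; @param path file path.
#' @return `readGenoTSV` returns a [GenotypeMatrix-class];
#'   `writeGenoTSV` returns `path` invisibly.
#' @export
writeGenoTSV <- function(x, path) {
  df <- data.frame(sample = sampleIds(x), genoCodes(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenoTSV
#' @export
readGenoTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  codes <- as.matrix(df[, -1, drop = FALSE])
  rownames(codes) <- df$sample
  ids <- colnames(codes)
  m <- regmatches(ids, regexec("^(.+):([0-9]+)_([ACGT]+)/([ACGT]+)$", ids))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("readGenoTSV: cannot parse variant id(s): ",
         paste(utils::head(ids[bad], 3), collapse = ", "))
  vt <- data.frame(chrom = vapply(m, `[`, "", 2),
                   pos = as.integer(vapply(m, `[`, "", 3)),
                   ref = vapply(m, `[`, "", 4),
                   alt = vapply(m, `[`, "", 5), stringsAsFactors = FALSE)
  GenotypeMatrix(codes, vt)
}

#' Long-format phenotype table IO
#'
#' Phenotypes are exchanged as long TSV with header
#' `id  trait  rep  value`; one row per (individual, trait, replicate).
#'
#' @param pheno data.frame with columns `id`, `trait`, `rep`, `value`.
#' @param path file path.
#' @export
writePhenoTSV <- function(pheno, path) {
  validatePhenotypes(pheno)
  utils::write.table(pheno[, c("id", "trait", "rep", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenoTSV
#' @export
readPhenoTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validatePhenotypes(df)
  df
}

#' Validate a long-format phenotype table
#'
#' Checks the column contract (`id`, `trait`, `rep`, `value`), that
#' (id, trait, rep) combinations are unique and that values are finite
#' or missing.
#'
#' @param pheno data.frame to validate.
#' @return `pheno`, invisibly, or an error.
#' @export
validatePhenotypes <- function(pheno) {
  need <- c("id", "trait", "rep", "value")
  if (!all(need %in% names(pheno)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  key <- paste(pheno$id, pheno$trait, pheno$rep, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (id, trait, rep) record(s) in phenotype table")
  v <- pheno$value
  if (any(!is.na(v) & !is.finite(v)))
    stop("non-finite phenotype value(s)")
  invisible(pheno)
}
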