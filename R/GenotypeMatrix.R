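#' Construct a GenotypeMatrix
#'
#' @param codes numeric/integer matrix, samples x variants, entries in
#'   {0, 1, 2, NA} counting alt alleles; rownames are sample ids.
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(
#'   matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("s1", "s2"), NULL)),
#'   data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G"))
#' nVariants(g)
#' @export
GenotypeMatrix <- function(codes, variants) {
  storage.mode(codes) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  if (is.null(colnames(codes)))
    colnames(codes) <- variantIds(variants)
  new("GenotypeMatrix", codes = codes, variants = variants)
}

variantIds <- function(variants) {
  paste0(variants$chrom, ":", variants$pos, "_", variants$ref, "/", variants$alt)
}

#' @describeIn GenotypeMatrix genotype code matrix (samples x variants)
#' @param x,object a `GenotypeMatrix`
#' @export
genoCodes <- function(x) x@codes

#' @describeIn GenotypeMatrix variant table (chrom, pos, ref, alt)
#' @export
variantInfo <- function(x) x@variants

#' @describeIn GenotypeMatrix sample ids
#' @export
sampleIds <- function(x) rownames(x@codes)

#' @describeIn GenotypeMatrix number of samples
#' @export
nSamples <- function(x) nrow(x@codes)

#' @describeIn GenotypeMatrix number of variants
#' @export
nVariants <- function(x) ncol(x@codes)

#' Per-variant allele frequencies and missingness
#'
#' `altAlleleFreq` is the alt-allele frequency on non-missing calls,
#' `minorAlleleFreq` folds it to min(p, 1 - p) (hence invariant to
#' swapping ref and alt), and `missingRate` is the fraction of missing
#' calls per variant.
#'
#' @param x a [GenotypeMatrix-class]
#' @return numeric vector, one entry per variant.
#' @export
altAlleleFreq <- function(x) {
  colMeans(x@codes, na.rm = TRUE) / 2
}

#' @rdname altAlleleFreq
#' @export
minorAlleleFreq <- function(x) {
  p <- altAlleleFreq(x)
  pmin(p, 1 - p)
}

#' @rdname altAlleleFreq
#' @export
missingRate <- function(x) {
  colMeans(is.na(x@codes))
}

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nSamples(object), "samples x",
      nVariants(object), "variants\n")
  nm <- sum(is.na(object@codes))
  cat("  chromosomes:", length(unique(object@variants$chrom)),
      "| missing calls:", nm, "\n")
})

#' Subset a GenotypeMatrix by samples (i) and variants (j)
#'
#' @param x a `GenotypeMatrix`
#' @param i,j sample and variant indices
#' @param drop ignored
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nVariants(x))
  GenotypeMatrix(x@codes[i, j, drop = FALSE], x@variants[j, , drop = FALSE])
})
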