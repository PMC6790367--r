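#' Filter variants on minor-allele frequency and missing rate
#'
#' Keeps variants with MAF >= `mafMin` (computed on non-missing calls)
#' AND missing fraction strictly below `missingMax` — the comparison
#' directions follow the usual "MAF >= 0.05 and missing rate < 15%"
#' convention, so a variant whose missing fraction equals `missingMax`
#' exactly is removed. Variants with all calls missing are removed and
#' counted in the message. Variant order is preserved; the operation is
#' idempotent.
#'
#' @param x a [GenotypeMatrix-class]
#' @param mafMin minimum minor-allele frequency in [0, 0.5].
#' @param missingMax exclusive upper bound on the missing fraction.
#' @return The filtered [GenotypeMatrix-class].
#' @export
filterVariants <- function(x, mafMin = 0.05, missingMax = 0.15) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, missingMax >= 0, missingMax <= 1)
  miss <- missingRate(x)
  allMissing <- miss == 1
  maf <- minorAlleleFreq(x)
  keep <- !allMissing & maf >= mafMin & miss < missingMax
  if (any(allMissing))
    message("filterVariants: removed ", sum(allMissing),
            " variant(s) with all calls missing")
  message("filterVariants: kept ", sum(keep), " of ", nVariants(x),
          " variants (MAF >= ", mafMin, ", missing < ", missingMax, ")")
  x[, keep]
}

#' Build an id x trait value table from long phenotypes
#'
#' @param pheno long phenotype data.frame (`id`, `trait`, `rep`, `value`).
#' @param level `"mean"` averages non-missing replicates per (id, trait);
#'   `"replicate"` preserves the records and returns the validated long
#'   table unchanged.
#' @return For `level = "mean"`, a numeric matrix with ids in rows and
#'   traits in columns (`NA` when all replicates are missing); for
#'   `level = "replicate"` the long data.frame.
#' @export
traitMatrix <- function(pheno, level = c("mean", "replicate")) {
  level <- match.arg(level)
  validatePhenotypes(pheno)
  if (level == "replicate") return(pheno)
  ids <- unique(pheno$id)
  traits <- unique(pheno$trait)
  out <- tapply(pheno$value, list(factor(pheno$id, ids),
                                  factor(pheno$trait, traits)),
                function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  m <- matrix(unlist(out), nrow = length(ids), ncol = length(traits),
              dimnames = list(ids, traits))
  m
}
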