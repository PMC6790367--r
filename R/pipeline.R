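#' End-to-end Q+K association scan of traits, GCA or SCA
#'
#' Composes the full association pipeline for one target and encoding:
#' variant filtering (MAF and missing rate), principal components on
#' complete variants (top `nPCs` as structure covariates), IBS kinship,
#' derivation of the scanned phenotype, genotype re-encoding, REML null
#' fit, EMMAX scan and the effective-number-of-tests threshold.
#'
#' Targets and their genotype/phenotype pairing:
#' \describe{
#'   \item{`parent-trait`}{male parents' own trait means, scanned on
#'     male-parent genotypes.}
#'   \item{`parent-gca`}{male-parent GCA treated as a new trait of each
#'     parent, scanned on male-parent genotypes. Only the male panel is
#'     scanned: a handful of female testers carries no mappable GCA
#'     variation, so the female margin is absorbed.}
#'   \item{`f1-trait`}{hybrid trait means scanned on F1 genotypes.}
#'   \item{`f1-sca`}{each hybrid's SCA treated as its phenotype, scanned
#'     on F1 genotypes (`scanParents = TRUE` switches the F1 targets to
#'     male-parent genotypes instead).}
#' }
#'
#' @param parents [GenotypeMatrix-class] of parental lines (must contain
#'   the design's male ids).
#' @param f1 [GenotypeMatrix-class] of hybrids (row ids = hybrid ids);
#'   may be `NULL` for parent targets.
#' @param pheno long phenotype data.frame.
#' @param design an [NCIIDesign-class].
#' @param trait trait name.
#' @param target one of `"parent-trait"`, `"parent-gca"`, `"f1-trait"`,
#'   `"f1-sca"`.
#' @param encoding genotype encoding for [encodeModel()].
#' @param nPCs number of principal-component covariates (default 5).
#' @param mafMin,missingMax variant filters (defaults 0.05 and 0.15).
#' @param windowSize window for [effectiveSnpCount()].
#' @param scanParents scan F1 targets on male-parent genotypes instead
#'   of F1 genotypes.
#' @return An [AssocResult-class].
#' @export
gwasPipeline <- function(parents, f1, pheno, design, trait,
                         target = c("parent-trait", "parent-gca",
                                    "f1-trait", "f1-sca"),
                         encoding = c("additive", "dominant", "recessive"),
                         nPCs = 5, mafMin = 0.05, missingMax = 0.15,
                         windowSize = 1000, scanParents = FALSE) {
  target <- match.arg(target)
  encoding <- match.arg(encoding)
  stopifnot(is(design, "NCIIDesign"))

  parentTarget <- target %in% c("parent-trait", "parent-gca") || scanParents
  if (parentTarget) {
    ids <- maleIds(design)
    G <- parents[match(ids, sampleIds(parents)), ]
  } else {
    if (is.null(f1)) stop("F1 genotypes required for target '", target, "'")
    ids <- crossMap(design)$hybrid
    G <- f1[match(ids, sampleIds(f1)), ]
  }

  y <- switch(target,
    "parent-trait" = {
      tm <- traitMatrix(pheno[pheno$trait == trait, , drop = FALSE])
      tm[match(ids, rownames(tm)), trait]
    },
    "parent-gca" = {
      ca <- computeGcaSca(cellMeans(pheno, design, trait), trait = trait)
      maleGCA(ca)[ids]
    },
    "f1-trait" = {
      tm <- traitMatrix(pheno[pheno$trait == trait, , drop = FALSE])
      hy <- crossMap(design)$hybrid
      tm[match(hy, rownames(tm)), trait]
    },
    "f1-sca" = {
      ca <- computeGcaSca(cellMeans(pheno, design, trait), trait = trait)
      scaByHybrid(ca, design)[crossMap(design)$hybrid]
    })
  if (anyNA(y)) stop("missing phenotype values for target '", target, "'")

  Gf <- filterVariants(G, mafMin = mafMin, missingMax = missingMax)
  complete <- Gf[, missingRate(Gf) == 0]
  pca <- pcaGenotypes(complete, nComponents = nPCs)
  X <- cbind(intercept = 1, pca$scores)
  K <- kinshipIBS(Gf)
  Genc <- encodeModel(Gf, encoding)
  nf <- fitNullLMM(y, X, K)
  scanAssoc(y, X, Genc, nf, encoding = encoding, windowSize = windowSize)
}
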