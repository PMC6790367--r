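#' @import methods
NULL

#' GenotypeMatrix: biallelic SNP genotypes for a panel of samples
#'
#' Container for a samples-by-variants matrix of alt-allele dosages
#' (0, 1, 2, `NA` for missing) together with the variant table
#' (chromosome, 1-based position, ref and alt alleles). Variant identity
#' throughout the package is the tuple (chromosome, position, ref, alt).
#'
#' @slot codes integer matrix, samples in rows (rownames are sample ids),
#'   variants in columns; entries count alt alleles, `NA` is missing.
#' @slot variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   one row per column of `codes`; positions strictly increasing within
#'   each chromosome.
#'
#' @seealso [GenotypeMatrix()] for the constructor, [readVCF()],
#'   [filterVariants()], [kinshipIBS()].
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(codes = "matrix", variants = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  cd <- object@codes
  vt <- object@variants
  if (ncol(cd) != nrow(vt))
    msgs <- c(msgs, "number of variant columns must match the variant table")
  if (is.null(rownames(cd)))
    msgs <- c(msgs, "codes must carry sample ids as rownames")
  else if (anyDuplicated(rownames(cd)))
    msgs <- c(msgs, "sample ids must be unique")
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(vt)))
    msgs <- c(msgs, "variant table needs columns chrom, pos, ref, alt")
  vals <- cd[!is.na(cd)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    msgs <- c(msgs, "genotype codes must be 0, 1, 2 or NA")
  if (nrow(vt) > 1 && all(c("chrom", "pos") %in% names(vt))) {
    ok <- all(tapply(vt$pos, vt$chrom, function(p) !is.unsorted(p, strictly = TRUE)))
    if (!isTRUE(ok))
      msgs <- c(msgs, "positions must be strictly increasing within chromosome")
  }
  if (all(c("ref", "alt") %in% names(vt)) && nrow(vt) &&
      any(nchar(vt$ref) != 1L | nchar(vt$alt) != 1L))
    msgs <- c(msgs, "only biallelic SNP records are allowed (single-base ref/alt)")
  if (length(msgs)) msgs else TRUE
})

#' NCIIDesign: a North Carolina II factorial mating design
#'
#' Describes a male-by-female factorial cross: the male panel, the female
#' testers, the cross map (which hybrid id corresponds to each male x
#' female combination) and the replication/block labels.
#'
#' @slot maleIds character, ids of the male parental lines.
#' @slot femaleIds character, ids of the female parental lines.
#' @slot crosses data.frame with columns `male`, `female`, `hybrid`.
#' @slot repLabels character, replication (block) labels.
#' @slot complete logical, whether the cross map is the full factorial.
#'
#' @seealso [nciiDesign()], [anovaNCII()], [computeGcaSca()].
#' @exportClass NCIIDesign
setClass("NCIIDesign",
  representation(maleIds = "character", femaleIds = "character",
                 crosses = "data.frame", repLabels = "character",
                 complete = "logical"))

setValidity("NCIIDesign", function(object) {
  msgs <- character()
  cr <- object@crosses
  if (!all(c("male", "female", "hybrid") %in% names(cr)))
    msgs <- c(msgs, "crosses needs columns male, female, hybrid")
  else {
    if (anyDuplicated(cr$hybrid))
      msgs <- c(msgs, "hybrid ids must be unique")
    if (!all(cr$male %in% object@maleIds) || !all(cr$female %in% object@femaleIds))
      msgs <- c(msgs, "crosses reference unknown parent ids")
    if (object@complete) {
      expected <- length(object@maleIds) * length(object@femaleIds)
      if (nrow(cr) != expected ||
          anyDuplicated(paste(cr$male, cr$female)))
        msgs <- c(msgs, "cross map marked complete but is not the full factorial")
    }
  }
  if (anyDuplicated(object@maleIds) || anyDuplicated(object@femaleIds))
    msgs <- c(msgs, "parent ids must be unique")
  if (length(intersect(object@maleIds, object@femaleIds)))
    msgs <- c(msgs, "male and female id sets must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' AnovaTable: NCII two-factor analysis of variance
#'
#' ANOVA of a balanced NCII trial with strata for replications, males,
#' females, the male x female interaction and error. Main-effect F
#' statistics use the interaction mean square as denominator; the
#' interaction and replications use the error mean square
#' (random-effects NCII convention).
#'
#' @slot table data.frame with one row per source (`df`, `ss`, `ms`,
#'   `fstat`, `p`, `sig`).
#' @slot r integer, number of replications.
#' @slot nMales,nFemales integer, factorial dimensions.
#' @slot trait character, trait analysed.
#' @exportClass AnovaTable
setClass("AnovaTable",
  representation(table = "data.frame", r = "integer",
                 nMales = "integer", nFemales = "integer",
                 trait = "character"))

#' VarianceComponents: method-of-moments NCII variance components
#'
#' Genetic and environmental variance components solved from the NCII
#' expected mean squares, with narrow-sense heritability
#' h2 = (additive male + female) / phenotypic and broad-sense
#' H2 = total genetic / phenotypic.
#'
#' @slot vf female additive variance; @slot vm male additive variance;
#' @slot vmf nonadditive (interaction) variance; @slot ve error variance;
#' @slot vg total genetic variance; @slot vp phenotypic variance;
#' @slot h2 narrow-sense heritability; @slot H2 broad-sense heritability.
#' @slot anyNegative logical flag: at least one raw component estimate
#'   was negative.
#' @slot truncated logical: negative estimates were truncated at zero.
#' @slot divisors named numeric, the mean-square divisors used.
#' @slot trait character.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(vf = "numeric", vm = "numeric", vmf = "numeric",
                 ve = "numeric", vg = "numeric", vp = "numeric",
                 h2 = "numeric", H2 = "numeric",
                 anyNegative = "logical", truncated = "logical",
                 divisors = "numeric", trait = "character"))

#' CombiningAbility: GCA/SCA decomposition of a cell-mean table
#'
#' Decomposes the male x female table of cross means for one trait into
#' the grand mean, male and female general combining abilities (GCA) and
#' the specific combining ability (SCA) matrix, so that
#' cell = grand + GCA_male + GCA_female + SCA for complete tables.
#'
#' @slot grandMean numeric(1).
#' @slot maleGCA,femaleGCA named numeric, each summing to zero for
#'   complete tables.
#' @slot sca matrix (males x females), rows and columns summing to zero
#'   for complete tables.
#' @slot cellMeans the input table.
#' @slot complete logical: no missing cells, zero-sum identities exact.
#' @slot trait character.
#' @exportClass CombiningAbility
setClass("CombiningAbility",
  representation(grandMean = "numeric", maleGCA = "numeric",
                 femaleGCA = "numeric", sca = "matrix",
                 cellMeans = "matrix", complete = "logical",
                 trait = "character"))

setValidity("CombiningAbility", function(object) {
  msgs <- character()
  if (!identical(dim(object@sca), dim(object@cellMeans)))
    msgs <- c(msgs, "sca and cellMeans must have identical dimensions")
  if (length(object@maleGCA) != nrow(object@sca) ||
      length(object@femaleGCA) != ncol(object@sca))
    msgs <- c(msgs, "GCA vector lengths must match the sca matrix")
  if (length(msgs)) msgs else TRUE
})

#' LMMNullFit: REML fit of the Q+K null mixed model
#'
#' Variance components of y = X b + u + e with u ~ N(0, sigmaG^2 K) and
#' e ~ N(0, sigmaE^2 I), estimated once under the null (no SNP) and
#' reused for every variant in an EMMAX-style scan. The spectral
#' decomposition of K is cached for the scan.
#'
#' @slot sigmaG2,sigmaE2 numeric variance components.
#' @slot delta numeric, sigmaE2 / sigmaG2.
#' @slot logREML numeric, restricted log-likelihood at the optimum.
#' @slot eigenK list with `values` and `vectors` of K.
#' @slot n,rankX integer, sample size and fixed-effect rank.
#' @exportClass LMMNullFit
setClass("LMMNullFit",
  representation(sigmaG2 = "numeric", sigmaE2 = "numeric",
                 delta = "numeric", logREML = "numeric",
                 eigenK = "list", n = "integer", rankX = "integer"))

#' AssocResult: per-variant association scan results
#'
#' @slot results data.frame with per-variant columns `chrom`, `pos`,
#'   `ref`, `alt`, `encoding`, `maf`, `beta`, `se`, `stat`, `p`,
#'   `note` (reason when a variant was skipped).
#' @slot encoding character, genotype encoding used
#'   (additive / dominant / recessive).
#' @slot M integer, variants tested; @slot Me numeric, effective number
#'   of independent tests; @slot threshold numeric, genome-wide
#'   significance level 0.05 / Me.
#' @slot nullFit the [LMMNullFit-class] behind the scan.
#' @exportClass AssocResult
setClass("AssocResult",
  representation(results = "data.frame", encoding = "character",
                 M = "integer", Me = "numeric", threshold = "numeric",
                 nullFit = "LMMNullFit"))

#' SimTruth: generative ground truth of a synthetic NCII dataset
#'
#' Records the quantities the generator knows exactly: QTL positions and
#' effects, subpopulation labels, and the GCA/SCA decomposition of the
#' noise-free F1 genetic values together with the realized narrow- and
#' broad-sense heritabilities.
#'
#' @slot qtlIndices integer, variant indices of the causal loci.
#' @slot additiveEffects,dominanceEffects numeric per-QTL effects (a_k,
#'   d_k in trait units).
#' @slot subpopLabels named character per parent sample.
#' @slot trueGcaMales,trueGcaFemales named numeric, each summing to 0.
#' @slot trueSca matrix (males x females), margins summing to 0.
#' @slot realizedH2narrow,realizedH2broad fractions in [0, 1].
#' @exportClass SimTruth
setClass("SimTruth",
  representation(qtlIndices = "integer", additiveEffects = "numeric",
                 dominanceEffects = "numeric", subpopLabels = "character",
                 trueGcaMales = "numeric", trueGcaFemales = "numeric",
                 trueSca = "matrix", realizedH2narrow = "numeric",
                 realizedH2broad = "numeric"))
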