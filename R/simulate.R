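#' Configuration for the synthetic NCII generator
#'
#' Defaults emulate a rice NCII trial: 96 inbred male lines drawn from 3
#' divergent subpopulations, 4 inbred female (male-sterile) testers, the
#' full 384-cross factorial, 3 replications, and a trait controlled by a
#' mix of additive and dominance QTLs.
#'
#' @param nMales,nFemales numbers of inbred male / female parents.
#' @param nSubpops number of subpopulations among the parents.
#' @param fst Balding-Nichols divergence of the subpopulations, in
#'   [0, 1); 0 means no structure.
#' @param nSnps number of biallelic SNPs.
#' @param mafRange range of ancestral allele frequencies (fractions in
#'   (0, 0.5], strictly increasing).
#' @param nQtlAdditive,nQtlDominance numbers of causal loci acting
#'   additively (effect a_k, d_k = 0) and through dominance (a_k = 0,
#'   effect d_k on heterozygotes).
#' @param additiveEffectSd,dominanceEffectSd standard deviations of the
#'   per-QTL effects a_k ~ N(0, sd) and d_k ~ N(0, sd), trait units.
#' @param nReps number of replications (blocks).
#' @param blockSd standard deviation of the per-replicate block effect,
#'   trait units.
#' @param residualSd standard deviation of the plot-level residual,
#'   trait units.
#' @param seed integer seed; one RNG stream per dataset, split by named
#'   purpose so each stage is independently reproducible.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nMales = 96, nFemales = 4, nSubpops = 3, fst = 0.2,
                      nSnps = 2000, mafRange = c(0.05, 0.5),
                      nQtlAdditive = 20, nQtlDominance = 10,
                      additiveEffectSd = 0.3, dominanceEffectSd = 0.3,
                      nReps = 3, blockSd = 0.5, residualSd = 1,
                      seed = 1L) {
  cfg <- list(nMales = as.integer(nMales), nFemales = as.integer(nFemales),
              nSubpops = as.integer(nSubpops), fst = fst,
              nSnps = as.integer(nSnps), mafRange = mafRange,
              nQtlAdditive = as.integer(nQtlAdditive),
              nQtlDominance = as.integer(nQtlDominance),
              additiveEffectSd = additiveEffectSd,
              dominanceEffectSd = dominanceEffectSd,
              nReps = as.integer(nReps), blockSd = blockSd,
              residualSd = residualSd, seed = as.integer(seed))
  counts <- c(cfg$nMales, cfg$nFemales, cfg$nSubpops, cfg$nSnps, cfg$nReps)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (cfg$nQtlAdditive < 0L || cfg$nQtlDominance < 0L)
    stop("QTL counts must be >= 0")
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must lie in [0, 1)")
  if (length(cfg$mafRange) != 2L || cfg$mafRange[1] <= 0 ||
      cfg$mafRange[2] > 0.5 || cfg$mafRange[1] >= cfg$mafRange[2])
    stop("mafRange must be a strictly increasing pair within (0, 0.5]")
  if (any(c(cfg$additiveEffectSd, cfg$dominanceEffectSd, cfg$blockSd,
            cfg$residualSd) < 0))
    stop("standard deviations must be >= 0")
  if (cfg$nSubpops > cfg$nMales) stop("nSubpops must not exceed nMales")
  if (cfg$nQtlAdditive + cfg$nQtlDominance > cfg$nSnps)
    stop("total QTL count must not exceed nSnps")
  class(cfg) <- "SimConfig"
  cfg
}

# deterministic sub-seed per named purpose, kept below 2^31
.substreamSeed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  (abs(seed) * 7919L + h) %% 2147483629L
}

#' Simulate inbred parental genotypes under population structure
#'
#' Allele frequencies follow a Balding-Nichols model: an ancestral
#' frequency p ~ Uniform(mafRange) per SNP, and per-subpopulation
#' frequencies Beta(p (1-F)/F, (1-p)(1-F)/F) with divergence F = `fst`
#' (F = 0 uses the ancestral frequency directly). Parents are fully
#' inbred: each line carries a single allele drawn at its subpopulation
#' frequency, so codes are 0 or 2 only. Males are split evenly across
#' the subpopulations; all female testers belong to subpopulation 1
#' (mirroring testers drawn from a single group). SNPs are spread over
#' 12 chromosomes at sorted uniform positions.
#'
#' @param cfg a [simConfig()] object.
#' @return list with `geno` (a [GenotypeMatrix-class] of all parents,
#'   males then females) and `subpops` (named character vector of
#'   subpopulation labels).
#' @export
simulateParents <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(.substreamSeed(cfg$seed, "parents"))
  nP <- cfg$nMales + cfg$nFemales
  ids <- c(sprintf("M%03d", seq_len(cfg$nMales)),
           sprintf("F%02d", seq_len(cfg$nFemales)))
  subM <- rep(seq_len(cfg$nSubpops), length.out = cfg$nMales)
  subM <- sort(subM)
  sub <- c(subM, rep(1L, cfg$nFemales))
  names(sub) <- ids

  pAnc <- stats::runif(cfg$nSnps, cfg$mafRange[1], cfg$mafRange[2])
  codes <- matrix(NA_integer_, nP, cfg$nSnps, dimnames = list(ids, NULL))
  for (s in seq_len(cfg$nSubpops)) {
    if (cfg$fst > 0) {
      shape <- (1 - cfg$fst) / cfg$fst
      ps <- stats::rbeta(cfg$nSnps, pAnc * shape, (1 - pAnc) * shape)
    } else ps <- pAnc
    rows <- which(sub == s)
    codes[rows, ] <- 2L * matrix(
      stats::rbinom(length(rows) * cfg$nSnps, 1L, rep(ps, each = length(rows))),
      length(rows), cfg$nSnps)
  }

  nChrom <- 12L
  chrom <- sort(rep(seq_len(nChrom), length.out = cfg$nSnps))
  pos <- unlist(lapply(split(seq_len(cfg$nSnps), chrom), function(i)
    sort(sample.int(3e7, length(i)))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$nSnps, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  vt <- data.frame(chrom = paste0("chr", chrom), pos = pos,
                   ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  list(geno = GenotypeMatrix(codes, vt),
       subpops = stats::setNames(paste0("pop", sub), ids))
}

#' Derive F1 genotypes from inbred parents and a cross map
#'
#' With fully inbred parents a single cross determines the F1 genotype:
#' code 1 where the parental codes differ (0 vs 2), the shared code
#' where they agree, and missing where either parent is missing.
#'
#' @param males,females [GenotypeMatrix-class] objects over the same
#'   variants (males and females may live in one matrix; rows are looked
#'   up by id).
#' @param design an [NCIIDesign-class].
#' @return A [GenotypeMatrix-class] with one row per hybrid, in cross-map
#'   order.
#' @export
deriveF1Genotypes <- function(males, females, design) {
  stopifnot(is(males, "GenotypeMatrix"), is(females, "GenotypeMatrix"),
            is(design, "NCIIDesign"))
  if (!identical(variantInfo(males)[c("chrom", "pos", "ref", "alt")],
                 variantInfo(females)[c("chrom", "pos", "ref", "alt")]))
    stop("male and female genotype matrices must share the variant set")
  for (g in list(males, females)) {
    het <- which(genoCodes(g) == 1L, arr.ind = TRUE)
    if (nrow(het)) {
      v <- variantInfo(g)[het[1, 2], ]
      stop("parent '", sampleIds(g)[het[1, 1]],
           "' is heterozygous at ", v$chrom, ":", v$pos,
           " — inbred parents required")
    }
  }
  cr <- crossMap(design)
  mi <- match(cr$male, sampleIds(males))
  fi <- match(cr$female, sampleIds(females))
  if (anyNA(mi) || anyNA(fi))
    stop("design references parents absent from the genotype matrices")
  f1 <- (genoCodes(males)[mi, , drop = FALSE] +
         genoCodes(females)[fi, , drop = FALSE]) / 2L
  rownames(f1) <- cr$hybrid
  GenotypeMatrix(f1, variantInfo(males))
}

#' Simulate NCII phenotypes with known genetic architecture
#'
#' The genetic value of an individual is
#' \eqn{\sum_k a_k x_k + \sum_k d_k 1[x_k = 1]} over the causal loci
#' (x_k the alt-allele dosage); an observed replicate adds a grand mean,
#' a block effect shared by all entries of that replicate, and a
#' Gaussian residual. Phenotypes are generated for the male parents and
#' all hybrids (female testers are male-sterile, so their own trait
#' values are unobservable, as in two-line hybrid breeding).
#'
#' The returned [SimTruth-class] carries the exact GCA/SCA decomposition
#' of the noise-free F1 genetic values and the realized heritabilities
#' \eqn{h^2 = (V_m + V_f) / (V_m + V_f + V_{mf} + \sigma_e^2)} and
#' \eqn{H^2 = (V_m + V_f + V_{mf}) / (V_m + V_f + V_{mf} + \sigma_e^2)},
#' where the V's are the sample variances (n-1 denominators) of the true
#' GCA/SCA effects — the quantities the NCII method-of-moments
#' estimators target. Block variance sits in the replications stratum
#' and therefore does not enter the phenotypic variance.
#'
#' @param parents list as returned by [simulateParents()] (or a
#'   [GenotypeMatrix-class] of all parents).
#' @param f1 hybrid genotypes from [deriveF1Genotypes()].
#' @param design an [NCIIDesign-class].
#' @param cfg the [simConfig()] used.
#' @param trait trait name for the phenotype table.
#' @param qtl,aEffects,dEffects optional explicit genetic architecture:
#'   variant indices and their additive / dominance effects (recycled
#'   checks apply). When supplied they replace the random draw — used to
#'   plant loci of known effect for validation experiments.
#' @return list with `pheno` (long data.frame) and `truth`
#'   (a [SimTruth-class]).
#' @export
simulatePhenotypes <- function(parents, f1, design, cfg, trait = "trait1",
                               qtl = NULL, aEffects = NULL, dEffects = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  geno <- if (is(parents, "GenotypeMatrix")) parents else parents$geno
  subpops <- if (is(parents, "GenotypeMatrix")) {
    stats::setNames(rep(NA_character_, nSamples(parents)), sampleIds(parents))
  } else parents$subpops

  set.seed(.substreamSeed(cfg$seed, "phenotypes"))
  if (!is.null(qtl)) {
    qtl <- as.integer(qtl)
    stopifnot(all(qtl >= 1), all(qtl <= nVariants(geno)))
    a <- if (is.null(aEffects)) numeric(length(qtl)) else as.numeric(aEffects)
    d <- if (is.null(dEffects)) numeric(length(qtl)) else as.numeric(dEffects)
    stopifnot(length(a) == length(qtl), length(d) == length(qtl))
  } else {
    nQtl <- cfg$nQtlAdditive + cfg$nQtlDominance
    qtl <- if (nQtl > 0) sort(sample.int(cfg$nSnps, nQtl)) else integer()
    isAdd <- seq_along(qtl) %in% sample(seq_along(qtl), cfg$nQtlAdditive)
    a <- as.numeric(ifelse(isAdd, stats::rnorm(nQtl, 0, cfg$additiveEffectSd), 0))
    d <- as.numeric(ifelse(!isAdd, stats::rnorm(nQtl, 0, cfg$dominanceEffectSd), 0))
  }

  geneticValue <- function(g) {
    x <- genoCodes(g)[, qtl, drop = FALSE]
    add <- x %*% a
    dom <- (x == 1L) %*% d
    drop(add + dom)
  }

  cr <- crossMap(design)
  gvMales <- geneticValue(geno[match(maleIds(design), sampleIds(geno)), ])
  gvF1 <- geneticValue(f1[match(cr$hybrid, sampleIds(f1)), ])

  # true GCA/SCA from the noise-free F1 genetic values, cell by cell
  cells <- matrix(NA_real_, length(maleIds(design)), length(femaleIds(design)),
                  dimnames = list(maleIds(design), femaleIds(design)))
  cells[cbind(match(cr$male, maleIds(design)),
              match(cr$female, femaleIds(design)))] <- gvF1
  grand <- mean(cells)
  gi <- rowMeans(cells) - grand
  gj <- colMeans(cells) - grand
  sca <- sweep(sweep(cells - grand, 1, gi), 2, gj)
  f <- length(maleIds(design)); m <- length(femaleIds(design))
  vM <- sum(gi^2) / max(f - 1, 1)
  vF <- sum(gj^2) / max(m - 1, 1)
  vMF <- sum(sca^2) / max((f - 1) * (m - 1), 1)
  vE <- cfg$residualSd^2
  vP <- vM + vF + vMF + vE
  h2 <- if (vP > 0) (vM + vF) / vP else 0
  H2 <- if (vP > 0) (vM + vF + vMF) / vP else 0

  blocks <- stats::rnorm(cfg$nReps, 0, cfg$blockSd)
  ids <- c(maleIds(design), cr$hybrid)
  gv <- c(gvMales, gvF1)
  grandMean <- 10                      # arbitrary positive baseline
  reps <- repLabels(design)[seq_len(cfg$nReps)]
  if (length(repLabels(design)) < cfg$nReps)
    reps <- paste0("rep", seq_len(cfg$nReps))
  pheno <- do.call(rbind, lapply(seq_len(cfg$nReps), function(k) {
    data.frame(id = ids, trait = trait, rep = reps[k],
               value = grandMean + gv + blocks[k] +
                 stats::rnorm(length(ids), 0, cfg$residualSd),
               stringsAsFactors = FALSE)
  }))

  truth <- new("SimTruth", qtlIndices = as.integer(qtl),
               additiveEffects = a, dominanceEffects = d,
               subpopLabels = subpops,
               trueGcaMales = gi, trueGcaFemales = gj, trueSca = sca,
               realizedH2narrow = h2, realizedH2broad = H2)
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete synthetic NCII dataset
#'
#' Convenience wrapper chaining [simulateParents()],
#' [deriveF1Genotypes()] and [simulatePhenotypes()] for the full
#' factorial design.
#'
#' @param cfg a [simConfig()].
#' @param trait trait name.
#' @param ... passed on to [simulatePhenotypes()] (e.g. an explicit
#'   planted architecture via `qtl`, `aEffects`, `dEffects`).
#' @return list with `parents` ([GenotypeMatrix-class]), `subpops`,
#'   `f1`, `design`, `pheno`, `truth`, `cfg`.
#' @examples
#' sim <- simulateNCII(simConfig(nMales = 8, nFemales = 2, nSnps = 50,
#'                               nQtlAdditive = 3, nQtlDominance = 1))
#' head(sim$pheno)
#' @export
simulateNCII <- function(cfg = simConfig(), trait = "trait1", ...) {
  par <- simulateParents(cfg)
  mIds <- grep("^M", sampleIds(par$geno), value = TRUE)
  fIds <- grep("^F", sampleIds(par$geno), value = TRUE)
  design <- nciiDesign(mIds, fIds, repLabels = paste0("rep", seq_len(cfg$nReps)))
  males <- par$geno[match(mIds, sampleIds(par$geno)), ]
  females <- par$geno[match(fIds, sampleIds(par$geno)), ]
  f1 <- deriveF1Genotypes(males, females, design)
  ph <- simulatePhenotypes(par, f1, design, cfg, trait = trait, ...)
  list(parents = par$geno, subpops = par$subpops, f1 = f1, design = design,
       pheno = ph$pheno, truth = ph$truth, cfg = cfg)
}

#' Write simulation ground truth as structured text (JSON)
#'
#' @param truth a [SimTruth-class]; @param path output path.
#' @export
writeSimTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  jsonlite::write_json(list(
    qtlIndices = truth@qtlIndices,
    additiveEffects = truth@additiveEffects,
    dominanceEffects = truth@dominanceEffects,
    subpopLabels = as.list(truth@subpopLabels),
    trueGcaMales = as.list(truth@trueGcaMales),
    trueGcaFemales = as.list(truth@trueGcaFemales),
    trueSca = truth@trueSca,
    realizedH2narrow = truth@realizedH2narrow,
    realizedH2broad = truth@realizedH2broad), path,
    digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@qtlIndices), "QTLs |",
      sum(object@additiveEffects != 0), "additive,",
      sum(object@dominanceEffects != 0), "dominance\n")
  cat(sprintf("  realized h2 = %.3f, H2 = %.3f\n",
              object@realizedH2narrow, object@realizedH2broad))
})
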