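#' Dominance index d/a at a locus
#'
#' From the phenotype means of the three genotype classes: the additive
#' effect is half the homozygote contrast, a = (mean(alt-hom) -
#' mean(ref-hom)) / 2. Two dominance deviations are reported: the
#' population-mean form d = mean(het) - mean(all), which is
#' frequency-dependent, and the classical midpoint form d = mean(het) -
#' (mean(ref-hom) + mean(alt-hom)) / 2. The headline ratio `da` uses the
#' population-mean form (`daClassical` carries the midpoint version);
#' |d/a| > 1 flags overdominance. Both forms require all three genotype
#' classes; a = 0 leaves the ratio undefined and flagged.
#'
#' @param y numeric phenotype vector.
#' @param g genotype codes 0/1/2 (additive encoding) aligned with `y`.
#' @return list with `classMeans`, `classCounts`, `a`, `d`,
#'   `dClassical`, `da`, `daClassical`, `overdominant`, `note`.
#' @export
dominanceIndex <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  cls <- factor(g, levels = c(0, 1, 2))
  counts <- as.integer(table(cls))
  means <- tapply(y, cls, mean)
  note <- ""
  if (any(counts == 0)) {
    note <- "missing genotype class: d undefined"
    return(list(classMeans = means, classCounts = counts,
                a = NA_real_, d = NA_real_, dClassical = NA_real_,
                da = NA_real_, daClassical = NA_real_,
                overdominant = NA, note = note))
  }
  a <- (means[[3]] - means[[1]]) / 2
  d <- means[[2]] - mean(y)
  dClassical <- means[[2]] - (means[[1]] + means[[3]]) / 2
  if (a == 0) {
    note <- "a = 0: d/a undefined"
    da <- daClassical <- NA_real_
    over <- NA
  } else {
    da <- d / a
    daClassical <- dClassical / a
    over <- abs(da) > 1
  }
  list(classMeans = means, classCounts = counts, a = a, d = d,
       dClassical = dClassical, da = da, daClassical = daClassical,
       overdominant = over, note = note)
}

#' Variance in a phenotype explained by one locus or a locus set
#'
#' For a single locus, the squared Pearson correlation between dosage
#' and phenotype. For a set of loci, the coefficient of determination
#' of the joint least-squares fit on the genotype-class indicator
#' variables (each locus entered as a factor), which is never smaller
#' than the largest single-locus r^2 of its members.
#'
#' @param y numeric phenotype.
#' @param G numeric vector (one locus) or matrix (samples x loci) of
#'   genotype codes.
#' @return list with `r2` (per-locus squared correlations) and
#'   `jointR2` (joint coefficient of determination).
#' @export
varianceExplained <- function(y, G) {
  G <- as.matrix(G)
  ok <- stats::complete.cases(y, G)
  y <- y[ok]; G <- G[ok, , drop = FALSE]
  if (stats::sd(y) == 0) stop("phenotype is constant")
  if (any(apply(G, 2, stats::sd) == 0)) stop("constant genotype column(s)")
  r2 <- apply(G, 2, function(g) stats::cor(y, g)^2)
  facs <- lapply(seq_len(ncol(G)), function(j) factor(G[, j]))
  mm <- stats::model.matrix(~ ., data = as.data.frame(facs,
    col.names = paste0("L", seq_len(ncol(G)))))
  if (length(y) < ncol(mm) + 2)
    stop("too few observations for the joint fit (need n >= p + 2)")
  fit <- stats::lm.fit(mm, y)
  jointR2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(r2 = r2, jointR2 = jointR2)
}

#' Genotype-frequency accumulation in extreme combining-ability groups
#'
#' Ranks individuals by a combining-ability score (GCA or SCA; ties
#' broken by id for determinism), takes the top and bottom groups, and
#' tabulates genotype-class counts and frequencies at the requested loci
#' in each group, together with the favourable-allele frequency contrast
#' between groups.
#'
#' @param scores named numeric vector (id -> GCA or SCA value).
#' @param x a [GenotypeMatrix-class] containing the scored ids.
#' @param loci variant indices (or ids as in `colnames(genoCodes(x))`).
#' @param topN,bottomN extreme group sizes (topN + bottomN <= length of
#'   scores).
#' @param favourable character vector, `"ref"` or `"alt"` per locus:
#'   which allele is favourable (e.g. set from the sign of a scan's
#'   effect estimates).
#' @return list with `table` (data.frame: locus, group, genotype class,
#'   count, frequency), `favFreq` (favourable-allele frequency per locus
#'   and group) and `favContrast` (top minus bottom).
#' @export
alleleAccumulation <- function(scores, x, loci, topN = 10, bottomN = 10,
                               favourable = NULL) {
  stopifnot(topN + bottomN <= length(scores))
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be named by sample id")
  if (!all(ids %in% sampleIds(x)))
    stop("score ids absent from the genotype matrix")
  if (is.character(loci)) {
    li <- match(loci, colnames(genoCodes(x)))
    if (anyNA(li)) stop("locus(i) absent from the genotype matrix: ",
                        paste(loci[is.na(li)], collapse = ", "))
    loci <- li
  }
  if (any(loci < 1 | loci > nVariants(x)))
    stop("locus index out of range")
  if (is.null(favourable)) favourable <- rep("alt", length(loci))
  stopifnot(length(favourable) == length(loci),
            all(favourable %in% c("ref", "alt")))

  ord <- order(-scores, ids)
  top <- ids[ord][seq_len(topN)]
  bottom <- rev(ids[ord])[seq_len(bottomN)]
  cd <- genoCodes(x)[, loci, drop = FALSE]
  rownames(cd) <- sampleIds(x)
  lociIds <- colnames(genoCodes(x))[loci]

  tab <- do.call(rbind, lapply(seq_along(loci), function(k) {
    do.call(rbind, lapply(list(top = top, bottom = bottom), function(grp) {
      g <- cd[grp, k]
      cnt <- table(factor(g, levels = c(0, 1, 2)))
      data.frame(locus = lociIds[k],
                 group = if (identical(grp, top)) "top" else "bottom",
                 class = c("ref-hom", "het", "alt-hom"),
                 count = as.integer(cnt),
                 frequency = as.numeric(cnt) / sum(cnt),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tab) <- NULL

  favFreqOne <- function(grp, k) {
    g <- cd[grp, k]
    g <- g[!is.na(g)]
    pAlt <- mean(g) / 2
    if (favourable[k] == "alt") pAlt else 1 - pAlt
  }
  favFreq <- data.frame(
    locus = lociIds,
    top = vapply(seq_along(loci), function(k) favFreqOne(top, k), 1),
    bottom = vapply(seq_along(loci), function(k) favFreqOne(bottom, k), 1),
    stringsAsFactors = FALSE)
  favFreq$contrast <- favFreq$top - favFreq$bottom
  list(table = tab, favFreq = favFreq,
       favContrast = stats::setNames(favFreq$contrast, lociIds))
}
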