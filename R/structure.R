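#' Identity-by-state kinship from shared SNP alleles
#'
#' K[s,t] is the proportion of SNP alleles shared identical-by-state,
#' averaged over the variants non-missing in both samples: per site the
#' sharing is (2 - |g_s - g_t|) / 2, i.e. 1 for identical genotypes, 1/2
#' for genotypes one allele apart, 0 for opposite homozygotes. Values
#' lie in [0, 1]; the diagonal is 1 for samples without missing data.
#' Pairs with no shared non-missing variant get `NA` with a warning.
#'
#' @param x a [GenotypeMatrix-class] (>= 2 samples).
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
kinshipIBS <- function(x) {
  stopifnot(nSamples(x) >= 2)
  cd <- genoCodes(x)
  obs <- !is.na(cd)
  i0 <- (cd == 0L) & obs; i1 <- (cd == 1L) & obs; i2 <- (cd == 2L) & obs
  i0[!obs] <- FALSE; i1[!obs] <- FALSE; i2[!obs] <- FALSE
  mode(i0) <- "numeric"; mode(i1) <- "numeric"; mode(i2) <- "numeric"
  # sum over shared sites of |g_s - g_t|:
  absdiff <- 2 * (i0 %*% t(i2) + i2 %*% t(i0)) +
    (i1 %*% t(i0 + i2) + (i0 + i2) %*% t(i1))
  nShared <- (obs * 1) %*% t(obs * 1)
  K <- 1 - absdiff / (2 * nShared)
  if (any(nShared == 0)) {
    warning("sample pair(s) with no shared non-missing variants: NA kinship")
    K[nShared == 0] <- NA_real_
  }
  dimnames(K) <- list(sampleIds(x), sampleIds(x))
  K
}

#' Principal components of a genotype matrix via SVD
#'
#' Singular-value decomposition of the column-mean-centered code matrix
#' (no unit-variance scaling). Scores are left singular vectors scaled
#' by the singular values; variance fractions are the squared singular
#' values over their sum. Each component is oriented so the loading
#' with the largest absolute value is positive, making signs
#' reproducible across linear-algebra backends. Missing data are not
#' allowed: subset to complete variants first (e.g.
#' `x[, missingRate(x) == 0]`).
#'
#' @param x a [GenotypeMatrix-class] without missing calls.
#' @param nComponents number of components to return.
#' @return list with `scores` (samples x components), `varFrac`
#'   (variance fractions, non-increasing) and `loadings`.
#' @export
pcaGenotypes <- function(x, nComponents = 5) {
  cd <- genoCodes(x)
  if (anyNA(cd))
    stop("missing genotypes present: subset to complete variants, e.g. ",
         "x[, missingRate(x) == 0]")
  ctr <- scale(cd, center = TRUE, scale = FALSE)
  k <- min(nComponents, nrow(cd) - 1L, ncol(cd))
  sv <- svd(ctr, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 1)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  loadings <- sweep(sv$v, 2, flip, `*`)
  rownames(scores) <- sampleIds(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, varFrac = sv$d^2 / sum(sv$d^2), loadings = loadings)
}

#' Linkage-disequilibrium decay curve
#'
#' Computes r^2 (squared Pearson correlation of genotype codes, the
#' dosage-based r^2 that matches haplotype r^2 exactly for fully
#' homozygous panels) for all within-chromosome variant pairs up to
#' `maxDistBp` apart, bins the pairs by distance, and reports the mean
#' r^2 per bin. The decay distance is the midpoint of the first bin
#' whose mean r^2 falls below `r2Threshold` (NA if none does).
#' Monomorphic variants are skipped.
#'
#' @param x a [GenotypeMatrix-class] with variant positions.
#' @param maxDistBp maximum pair distance in bp.
#' @param binWidthBp distance bin width in bp.
#' @param r2Threshold decay threshold on mean r^2 (default 0.2).
#' @return list with `bins` (data.frame: `start`, `end`, `mid`,
#'   `meanR2`, `nPairs`) and `decayDistance` (bp).
#' @export
ldDecay <- function(x, maxDistBp = 1e6, binWidthBp = 1e4, r2Threshold = 0.2) {
  vt <- variantInfo(x)
  cd <- genoCodes(x)
  poly <- apply(cd, 2, function(g) stats::sd(g, na.rm = TRUE) > 0)
  poly[is.na(poly)] <- FALSE
  dists <- numeric(0); r2s <- numeric(0)
  for (ch in unique(vt$chrom)) {
    j <- which(vt$chrom == ch & poly)
    if (length(j) < 2) next
    pos <- vt$pos[j]
    sub <- cd[, j, drop = FALSE]
    for (a in seq_len(length(j) - 1)) {
      within <- which(pos > pos[a] & pos - pos[a] <= maxDistBp)
      if (!length(within)) next
      r <- suppressWarnings(
        stats::cor(sub[, a], sub[, within, drop = FALSE],
                   use = "pairwise.complete.obs"))
      ok <- !is.na(r)
      dists <- c(dists, (pos[within] - pos[a])[ok])
      r2s <- c(r2s, (r[ok])^2)
    }
  }
  breaks <- seq(0, maxDistBp + binWidthBp, by = binWidthBp)
  bin <- cut(dists, breaks, right = TRUE)
  meanR2 <- tapply(r2s, bin, mean)
  nPairs <- tapply(r2s, bin, length)
  bins <- data.frame(start = breaks[-length(breaks)], end = breaks[-1],
                     mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                     meanR2 = as.numeric(meanR2),
                     nPairs = ifelse(is.na(nPairs), 0L, as.integer(nPairs)),
                     row.names = NULL)
  below <- which(!is.na(bins$meanR2) & bins$meanR2 < r2Threshold)
  list(bins = bins,
       decayDistance = if (length(below)) bins$mid[below[1]] else NA_real_)
}
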