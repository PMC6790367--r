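#' Re-encode genotypes under additive, dominant or recessive models
#'
#' The additive encoding leaves alt-allele dosages unchanged. Under the
#' dominant encoding heterozygotes behave as alt homozygotes (code
#' 1 -> 2: the alt allele acts dominant); under the recessive encoding
#' heterozygotes behave as ref homozygotes (code 1 -> 0: the alt allele
#' acts recessive). Missing calls are preserved.
#'
#' @param x a [GenotypeMatrix-class].
#' @param model one of `"additive"`, `"dominant"`, `"recessive"`.
#' @return A [GenotypeMatrix-class] with recoded genotypes.
#' @export
encodeModel <- function(x, model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  cd <- genoCodes(x)
  if (model == "dominant") cd[cd == 1L] <- 2L
  if (model == "recessive") cd[cd == 1L] <- 0L
  GenotypeMatrix(cd, variantInfo(x))
}

#' REML fit of the Q+K null mixed model
#'
#' Fits y = X b + u + e with u ~ N(0, sigmaG^2 K), e ~ N(0, sigmaE^2 I)
#' by restricted maximum likelihood. The likelihood is profiled onto the
#' single ratio delta = sigmaE^2 / sigmaG^2 through one eigendecomposition
#' of the projected kinship, and delta is optimized on a 100-point grid
#' over log(delta) in [-10, 10] refined by golden-section search to
#' tolerance 1e-6. The spectral decomposition of K itself is cached for
#' the subsequent per-variant scan.
#'
#' @param y numeric response (no missing values, non-constant).
#' @param X fixed-effect design matrix including the intercept (and
#'   typically the top principal components as structure covariates).
#' @param K kinship matrix, positive semi-definite.
#' @return An [LMMNullFit-class].
#' @export
fitNullLMM <- function(y, X, K) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (anyNA(y) || anyNA(X) || anyNA(K)) stop("missing values not allowed")
  if (stats::sd(y) == 0) stop("y is constant")
  K <- (K + t(K)) / 2
  eK <- eigen(K, symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(abs(eK$values)))
    stop("K is not positive semi-definite within tolerance")
  qx <- qr(X)
  q <- qx$rank
  if (n < q + 2) stop("need n >= rank(X) + 2")

  # restricted likelihood on the (n - q)-dim complement of col(X)
  Q2 <- qr.Q(qx, complete = TRUE)[, (q + 1):n, drop = FALSE]
  eS <- eigen(crossprod(Q2, K %*% Q2), symmetric = TRUE)
  xi <- pmax(eS$values, 0)
  eta <- crossprod(eS$vectors, crossprod(Q2, y))
  m <- n - q

  negll <- function(logDelta) {
    dl <- exp(logDelta)
    w <- xi + dl
    ss <- sum(eta^2 / w)
    -0.5 * (m * (log(m / (2 * pi)) - 1 - log(ss)) - sum(log(w)))
  }
  grid <- seq(-10, 10, length.out = 100)
  vals <- vapply(grid, negll, 1)
  i0 <- which.min(vals)
  lo <- grid[max(i0 - 1, 1)]; hi <- grid[min(i0 + 1, length(grid))]
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-6)
  delta <- exp(opt$minimum)
  sigmaG2 <- sum(eta^2 / (xi + delta)) / m
  sigmaE2 <- delta * sigmaG2
  new("LMMNullFit", sigmaG2 = sigmaG2, sigmaE2 = sigmaE2, delta = delta,
      logREML = -opt$objective,
      eigenK = list(values = eK$values, vectors = eK$vectors),
      n = as.integer(n), rankX = as.integer(q))
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML criterion of the null model at arbitrary
#' (sigmaG^2, sigmaE^2); used to verify that the fitted optimum
#' dominates other points.
#'
#' @param y,X,K as in [fitNullLMM()].
#' @param sigmaG2,sigmaE2 variance components (sigmaG2 > 0).
#' @return numeric restricted log-likelihood.
#' @export
logRestrictedLik <- function(y, X, K, sigmaG2, sigmaE2) {
  n <- length(y)
  qx <- qr(as.matrix(X))
  q <- qx$rank
  Q2 <- qr.Q(qx, complete = TRUE)[, (q + 1):n, drop = FALSE]
  eS <- eigen(crossprod(Q2, ((K + t(K)) / 2) %*% Q2), symmetric = TRUE)
  xi <- pmax(eS$values, 0)
  eta <- crossprod(eS$vectors, crossprod(Q2, y))
  w <- sigmaG2 * xi + sigmaE2
  -0.5 * (sum(log(w)) + sum(eta^2 / w) + (n - q) * log(2 * pi))
}

#' EMMAX-style per-variant association scan
#'
#' Holds the variance components at their null-model REML estimates and
#' tests each variant by generalized least squares under the fixed
#' covariance Sigma = sigmaG^2 K + sigmaE^2 I: effect estimate, standard
#' error, t statistic on n - rank(X) - 1 degrees of freedom and
#' two-sided p-value. Variants that are monomorphic (zero variance after
#' encoding) or perfectly collinear with the covariates are reported
#' missing with a reason rather than dropped silently. Missing genotype
#' calls within a tested variant are mean-imputed for testing (the MAF
#' column is computed before imputation). An `"exact"` mode refits the
#' variance components by REML for every variant, for small-instance
#' cross-validation of the approximation.
#'
#' @param y numeric response.
#' @param X covariate matrix including intercept.
#' @param Gmat a [GenotypeMatrix-class] of (possibly re-encoded)
#'   genotypes for the same samples, in the same row order.
#' @param nullFit an [LMMNullFit-class] from [fitNullLMM()] (ignored in
#'   `method = "exact"`).
#' @param K kinship matrix; required for `method = "exact"`.
#' @param encoding label stored with the results.
#' @param method `"emmax"` (default) or `"exact"`.
#' @param windowSize window size for [effectiveSnpCount()].
#' @return An [AssocResult-class].
#' @export
scanAssoc <- function(y, X, Gmat, nullFit, K = NULL,
                      encoding = "additive",
                      method = c("emmax", "exact"), windowSize = 1000) {
  method <- match.arg(method)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(is(Gmat, "GenotypeMatrix"), nSamples(Gmat) == n, nrow(X) == n)
  cd <- genoCodes(Gmat)
  maf <- minorAlleleFreq(Gmat)
  M <- nVariants(Gmat)
  q <- qr(X)$rank
  df <- n - q - 1
  beta <- se <- stat <- p <- rep(NA_real_, M)
  note <- rep("", M)

  if (method == "emmax") {
    stopifnot(is(nullFit, "LMMNullFit"), nullFit@n == n)
    U <- nullFit@eigenK$vectors
    w <- 1 / sqrt(pmax(nullFit@sigmaG2 * nullFit@eigenK$values, 0) +
                  nullFit@sigmaE2)
    ys <- w * crossprod(U, y)
    Xs <- w * crossprod(U, X)
    qXs <- qr(Xs)
    ry <- qr.resid(qXs, ys)
    Gimp <- cd
    mu <- colMeans(cd, na.rm = TRUE)
    naIdx <- which(is.na(Gimp))
    if (length(naIdx))
      Gimp[naIdx] <- mu[((naIdx - 1) %/% n) + 1]
    varG <- apply(Gimp, 2, stats::var)
    zero <- is.na(varG) | varG == 0
    note[zero] <- "monomorphic after encoding"
    if (any(!zero)) {
      Gs <- w * crossprod(U, Gimp[, !zero, drop = FALSE])
      rG <- qr.resid(qXs, Gs)
      gg <- colSums(rG^2)
      collinear <- gg < 1e-12 * colSums(Gs^2)
      gy <- colSums(rG * drop(ry))
      b <- gy / gg
      rss <- sum(ry^2) - b * gy
      s2 <- rss / df
      seb <- sqrt(s2 / gg)
      tt <- b / seb
      pv <- 2 * stats::pt(-abs(tt), df)
      idx <- which(!zero)
      beta[idx] <- b; se[idx] <- seb; stat[idx] <- tt; p[idx] <- pv
      if (any(collinear)) {
        ci <- idx[collinear]
        beta[ci] <- se[ci] <- stat[ci] <- p[ci] <- NA_real_
        note[ci] <- "collinear with covariates"
      }
    }
  } else {
    if (is.null(K)) stop("method = 'exact' requires K")
    for (j in seq_len(M)) {
      g <- cd[, j]
      if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
      if (stats::var(g) == 0) { note[j] <- "monomorphic after encoding"; next }
      Xj <- cbind(X, g)
      if (qr(Xj)$rank <= q) { note[j] <- "collinear with covariates"; next }
      fitj <- fitNullLMM(y, Xj, K)
      U <- fitj@eigenK$vectors
      w <- 1 / sqrt(pmax(fitj@sigmaG2 * fitj@eigenK$values, 0) + fitj@sigmaE2)
      ys <- w * crossprod(U, y)
      Xjs <- w * crossprod(U, Xj)
      fit <- stats::lm.fit(Xjs, drop(ys))
      cf <- fit$coefficients
      rss <- sum(fit$residuals^2)
      XtX <- chol2inv(chol(crossprod(Xjs)))
      sej <- sqrt(rss / df * XtX[ncol(Xj), ncol(Xj)])
      beta[j] <- cf[length(cf)]
      se[j] <- sej
      stat[j] <- beta[j] / sej
      p[j] <- 2 * stats::pt(-abs(stat[j]), df)
    }
  }

  esc <- effectiveSnpCount(Gmat, windowSize = windowSize)
  vt <- variantInfo(Gmat)
  res <- data.frame(chrom = vt$chrom, pos = vt$pos, ref = vt$ref,
                    alt = vt$alt, encoding = encoding, maf = maf,
                    beta = beta, se = se, stat = stat, p = p, note = note,
                    stringsAsFactors = FALSE)
  nf <- if (method == "emmax") nullFit else
    new("LMMNullFit", sigmaG2 = NA_real_, sigmaE2 = NA_real_,
        delta = NA_real_, logREML = NA_real_, eigenK = list(),
        n = as.integer(n), rankX = as.integer(q))
  new("AssocResult", results = res, encoding = encoding,
      M = as.integer(M), Me = esc$Me, threshold = esc$threshold,
      nullFit = nf)
}

#' @describeIn scanAssoc per-variant results data.frame
#' @param x an `AssocResult`
#' @export
assocResults <- function(x) x@results

#' @describeIn scanAssoc the genome-wide significance threshold 0.05/Me
#' @export
assocThreshold <- function(x) x@threshold

#' @export
setMethod("show", "AssocResult", function(object) {
  cat("AssocResult (", object@encoding, "): ", object@M, " variants, Me = ",
      sprintf("%.1f", object@Me), ", threshold = ",
      sprintf("%.3g", object@threshold), "\n", sep = "")
  ok <- !is.na(object@results$p)
  if (any(ok))
    cat("  min p =", sprintf("%.3g", min(object@results$p[ok])),
        "|", sum(object@results$p[ok] < object@threshold, na.rm = TRUE),
        "variant(s) below threshold\n")
})

#' Effective number of independent tests and significance threshold
#'
#' Computes the effective number of independent SNPs Me from the
#' eigenvalues of the variant correlation matrix in non-overlapping
#' windows of consecutive variants (per chromosome): each window
#' contributes \eqn{\sum_i (1[\lambda_i \ge 1] + (\lambda_i -
#' \lfloor \lambda_i \rfloor))}, the eigenvalue-based effective-count
#' rule of the Li-Ji family. Fully correlated windows contribute ~1,
#' independent ones ~ their size; a single-variant window contributes
#' exactly 1. The genome-wide threshold is the Bonferroni level with M
#' replaced by Me: alpha / Me at the nominal alpha = 0.05.
#'
#' Monomorphic variants carry no test and contribute 0. Missing calls
#' are mean-imputed for the correlation matrix.
#'
#' @param x a [GenotypeMatrix-class] (typically already encoded).
#' @param windowSize variants per window (default 1000).
#' @param alpha nominal genome-wide level.
#' @return list with `Me`, `M`, and `threshold` = alpha / Me.
#' @export
effectiveSnpCount <- function(x, windowSize = 1000, alpha = 0.05) {
  stopifnot(nVariants(x) >= 1)
  cd <- genoCodes(x)
  vt <- variantInfo(x)
  Me <- 0
  for (ch in unique(vt$chrom)) {
    j <- which(vt$chrom == ch)
    starts <- seq(1, length(j), by = windowSize)
    for (s in starts) {
      jj <- j[s:min(s + windowSize - 1, length(j))]
      sub <- cd[, jj, drop = FALSE]
      mu <- colMeans(sub, na.rm = TRUE)
      na <- which(is.na(sub))
      if (length(na)) sub[na] <- mu[((na - 1) %/% nrow(sub)) + 1]
      v <- apply(sub, 2, stats::var)
      sub <- sub[, v > 0, drop = FALSE]
      if (!ncol(sub)) next
      if (ncol(sub) == 1) { Me <- Me + 1; next }
      lam <- eigen(stats::cor(sub), symmetric = TRUE, only.values = TRUE)$values
      lam <- pmax(lam, 0)
      Me <- Me + sum((lam >= 1) + (lam - floor(lam)))
    }
  }
  list(Me = Me, M = nVariants(x), threshold = alpha / max(Me, 1))
}
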