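test_that("genotype encodings recode heterozygotes as specified", {
  g <- toyGenotype(matrix(c(0L, 1L, 2L, 1L), 4, 1))
  expect_equal(genoCodes(encodeModel(g, "additive")), genoCodes(g))
  expect_equal(unname(genoCodes(encodeModel(g, "dominant"))[, 1]),
               c(0L, 2L, 2L, 2L))
  expect_equal(unname(genoCodes(encodeModel(g, "recessive"))[, 1]),
               c(0L, 0L, 2L, 0L))
  gm <- toyGenotype(matrix(c(0L, 1L, NA, 2L), 4, 1))
  expect_true(is.na(genoCodes(encodeModel(gm, "dominant"))[3, 1]))
  expect_error(encodeModel(g, "codominant"))
})

test_that("null REML recovers variance components on a random PSD kinship", {
  set.seed(101)
  n <- 300
  ratios <- vapply(1:10, function(i) {
    Z <- matrix(rnorm(n * 40), n, 40)
    K <- tcrossprod(Z) / 40
    K <- K / mean(diag(K))
    eK <- eigen(K, symmetric = TRUE)
    u <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * rnorm(n)) * sqrt(2)
    y <- drop(5 + u + rnorm(n, 0, 1))
    fit <- fitNullLMM(y, cbind(1, rnorm(n)), K)
    c(fit@sigmaG2 / 2, fit@sigmaE2 / 1)
  }, c(1, 1))
  expect_lt(abs(mean(ratios[1, ]) - 1), 0.3)
  expect_lt(abs(mean(ratios[2, ]) - 1), 0.3)
})

test_that("with identity kinship, total variance matches OLS residual variance", {
  set.seed(5)
  n <- 120
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, 0.5) + rnorm(n, 0, 1.3))
  fit <- fitNullLMM(y, X, diag(n))
  ols <- sum(lm.fit(X, y)$residuals^2) / (n - 2)
  expect_equal(fit@sigmaG2 + fit@sigmaE2, ols, tolerance = 1e-4)
})

test_that("the REML optimum dominates random variance-component points", {
  set.seed(7)
  n <- 80
  Z <- matrix(rnorm(n * 30), n, 30)
  K <- tcrossprod(Z) / 30
  X <- cbind(rep(1, n))
  y <- rnorm(n) + drop(Z %*% rnorm(30, 0, 0.2))
  fit <- fitNullLMM(y, X, K)
  llOpt <- logRestrictedLik(y, X, K, fit@sigmaG2, fit@sigmaE2)
  set.seed(8)
  for (i in 1:50) {
    ll <- logRestrictedLik(y, X, K, runif(1, 0.01, 5), runif(1, 0.01, 5))
    expect_lte(ll, llOpt + 1e-6)
  }
})

test_that("scan equals OLS with identity kinship and intercept only", {
  set.seed(11)
  n <- 200; M <- 500
  G <- randomGenotype(n, M, maf = 0.3, seed = 11)
  y <- rnorm(n) + 0.3 * genoCodes(G)[, 1]
  X <- cbind(rep(1, n))
  fit <- fitNullLMM(y, X, diag(n))
  res <- assocResults(scanAssoc(y, X, G, fit))
  pOLS <- vapply(seq_len(M), function(j) {
    g <- genoCodes(G)[, j]
    if (var(g) == 0) return(NA_real_)
    summary(lm(y ~ g))$coefficients["g", 4]
  }, 1)
  ok <- !is.na(pOLS)
  expect_equal(res$p[ok], pOLS[ok], tolerance = 1e-8)
})

test_that("scan matches the exact per-variant REML mode on a small instance", {
  set.seed(13)
  n <- 60; M <- 20
  G <- randomGenotype(n, M, maf = 0.3, seed = 13)
  Z <- matrix(rnorm(n * 20), n, 20)
  K <- tcrossprod(Z) / 20; K <- K / mean(diag(K))
  y <- rnorm(n) + 0.5 * genoCodes(G)[, 3]
  X <- cbind(rep(1, n))
  fit <- fitNullLMM(y, X, K)
  emmax <- assocResults(scanAssoc(y, X, G, fit))
  exact <- assocResults(scanAssoc(y, X, G, fit, K = K, method = "exact"))
  ok <- !is.na(emmax$p) & !is.na(exact$p)
  expect_gt(cor(-log10(emmax$p[ok]), -log10(exact$p[ok])), 0.99)
})

test_that("permutation-null p-values are uniform and lambda_GC is calibrated", {
  set.seed(17)
  n <- 300; M <- 2000
  G <- randomGenotype(n, M, maf = 0.25, seed = 17)
  y <- rnorm(n)
  X <- cbind(rep(1, n))
  K <- kinshipIBS(G)
  fit <- fitNullLMM(y, X, K)
  res <- assocResults(scanAssoc(y, X, G, fit))
  p <- res$p[!is.na(res$p)]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  lambda <- median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
  expect_gt(lambda, 0.9)
  expect_lt(lambda, 1.1)
})

test_that("scan statistics are invariant to shifting the phenotype", {
  set.seed(19)
  n <- 80
  G <- randomGenotype(n, 50, seed = 19)
  y <- rnorm(n)
  X <- cbind(rep(1, n))
  K <- kinshipIBS(G)
  f1 <- fitNullLMM(y, X, K)
  f2 <- fitNullLMM(y + 100, X, K)
  r1 <- assocResults(scanAssoc(y, X, G, f1))
  r2 <- assocResults(scanAssoc(y + 100, X, G, f2))
  expect_equal(r1$stat, r2$stat, tolerance = 1e-6)
})

test_that("duplicated variants get identical statistics; monomorphic are flagged", {
  set.seed(23)
  n <- 60
  base <- randomGenotype(n, 5, seed = 23)
  codes <- cbind(genoCodes(base), genoCodes(base)[, 1], 1L)
  g <- toyGenotype(codes)
  y <- rnorm(n)
  X <- cbind(rep(1, n))
  fit <- fitNullLMM(y, X, diag(n))
  res <- assocResults(scanAssoc(y, X, g, fit))
  expect_equal(res$p[6], res$p[1])
  expect_true(is.na(res$p[7]))
  expect_match(res$note[7], "monomorphic")
})

test_that("effective test count behaves at the two LD extremes", {
  # independent variants: Me/M near 1
  gi <- randomGenotype(400, 100, maf = 0.3, seed = 29)
  me <- effectiveSnpCount(gi, windowSize = 100)
  expect_gt(me$Me / me$M, 0.9)
  expect_lte(me$Me, me$M)
  # all columns identical: Me = 1
  one <- randomGenotype(50, 1, seed = 31)
  dup <- toyGenotype(genoCodes(one)[, rep(1, 20)])
  med <- effectiveSnpCount(dup, windowSize = 20)
  expect_equal(med$Me, 1)
  expect_equal(med$threshold, 0.05)
  # single-variant window contributes exactly 1
  m1 <- effectiveSnpCount(one)
  expect_equal(m1$Me, 1)
})

test_that("threshold tightens as LD weakens", {
  set.seed(33)
  n <- 200
  indep <- randomGenotype(n, 60, seed = 33)
  # correlated blocks: 6 master columns copied 10x with small perturbation
  master <- genoCodes(randomGenotype(n, 6, seed = 34))
  blocky <- master[, rep(1:6, each = 10)]
  flip <- matrix(runif(length(blocky)) < 0.02, n, 60)
  blocky[flip] <- sample(0:2, sum(flip), replace = TRUE)
  gBlocky <- toyGenotype(blocky)
  tIndep <- effectiveSnpCount(indep, windowSize = 60)$threshold
  tBlocky <- effectiveSnpCount(gBlocky, windowSize = 60)$threshold
  expect_lt(tIndep, tBlocky)
})

test_that("without QTLs the Me threshold controls family-wise error", {
  hits <- vapply(1:20, function(s) {
    cfg <- simConfig(nMales = 60, nFemales = 2, nSnps = 300, nSubpops = 2,
                     fst = 0.1, nQtlAdditive = 0, nQtlDominance = 0,
                     seed = 7000 + s)
    sim <- simulateNCII(cfg)
    res <- suppressMessages(gwasPipeline(sim$parents, NULL, sim$pheno,
                                         sim$design, "trait1",
                                         target = "parent-trait",
                                         encoding = "additive"))
    tab <- assocResults(res)
    sum(tab$p < assocThreshold(res), na.rm = TRUE)
  }, 1)
  expect_gte(mean(hits == 0), 0.95)
})

test_that("pipeline recovers a planted additive QTL in the parent-GCA scan", {
  cfg <- simConfig(nMales = 60, nFemales = 4, nSnps = 400, nSubpops = 2,
                   fst = 0.1, nQtlAdditive = 1, nQtlDominance = 0,
                   additiveEffectSd = 2, residualSd = 0.5, seed = 71)
  sim <- simulateNCII(cfg)
  res <- suppressMessages(gwasPipeline(sim$parents, sim$f1, sim$pheno,
                                       sim$design, "trait1",
                                       target = "parent-gca",
                                       encoding = "additive"))
  tab <- assocResults(res)
  qtl <- variantInfo(sim$parents)[sim$truth@qtlIndices, ]
  hit <- tab[which.min(tab$p), ]
  expect_equal(hit$chrom, qtl$chrom)
  expect_equal(hit$pos, qtl$pos)
})
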