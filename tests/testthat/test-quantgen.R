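test_that("2x2x2 toy ANOVA equals the brute-force sums-of-squares oracle", {
  toy <- toy222Pheno()
  at <- anovaNCII(toy$pheno, toy$design, "t")
  oracle <- bruteForceSS(toy$pheno, toy$design, "t")
  tab <- anovaTable(at)
  ss <- setNames(tab$ss, tab$source)
  expect_equal(ss[["Males"]], oracle$males)
  expect_equal(ss[["Females"]], oracle$females)
  expect_equal(ss[["Males x Females"]], oracle$mf)
  expect_equal(ss[["Replications"]], oracle$rep)
  expect_equal(ss[["Error"]], oracle$error)
  expect_equal(tab$df, c(1, 1, 1, 1, 3, 7))
})

test_that("ANOVA SS decomposition is additive on balanced synthetic data", {
  sim <- simulateNCII(simConfig(nMales = 10, nFemales = 3, nSnps = 60,
                                seed = 31))
  at <- anovaNCII(sim$pheno, sim$design, "trait1")
  tab <- anovaTable(at)
  expect_equal(sum(tab$ss[tab$source != "Total"]),
               tab$ss[tab$source == "Total"])
  # cross-check the stratum SS against aov()
  cr <- crossMap(sim$design)
  ph <- sim$pheno[sim$pheno$id %in% cr$hybrid, ]
  idx <- match(ph$id, cr$hybrid)
  df <- data.frame(y = ph$value, male = factor(cr$male[idx]),
                   female = factor(cr$female[idx]), rep = factor(ph$rep))
  fit <- aov(y ~ rep + male * female, df)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(tab$ss[1:5], unname(ss), tolerance = 1e-8)
})

test_that("constant data gives all-zero SS and missing F", {
  toy <- toy222Pheno()
  toy$pheno$value <- 5
  at <- anovaNCII(toy$pheno, toy$design, "t")
  tab <- anovaTable(at)
  expect_equal(tab$ss, rep(0, 6))
  expect_true(all(is.na(tab$fstat)))
})

test_that("unbalanced input is rejected with a pointer to the cell-mean route", {
  toy <- toy222Pheno()
  expect_error(anovaNCII(toy$pheno[-1, ], toy$design, "t"), "computeGcaSca")
})

test_that("main-effect F uses the interaction MS as denominator", {
  sim <- simulateNCII(simConfig(nMales = 8, nFemales = 3, nSnps = 50,
                                seed = 41))
  tab <- anovaTable(anovaNCII(sim$pheno, sim$design, "trait1"))
  ms <- setNames(tab$ms, tab$source)
  fs <- setNames(tab$fstat, tab$source)
  expect_equal(fs[["Males"]], ms[["Males"]] / ms[["Males x Females"]])
  expect_equal(fs[["Females"]], ms[["Females"]] / ms[["Males x Females"]])
  expect_equal(fs[["Males x Females"]], ms[["Males x Females"]] / ms[["Error"]])
})

test_that("variance components reproduce published worked values", {
  ref <- riceAnovaReference()
  # interaction components recomputable at printed precision wherever the
  # printed mean squares were not whole-number rounded
  for (tr in c("panicle_length", "effective_panicles", "seed_setting_rate",
               "grain_weight", "grain_width")) {
    row <- ref[ref$trait == tr, ]
    vc <- suppressWarnings(varianceComponentsFromMS(
      row$ms_males, row$ms_females, row$ms_mf, row$ve,
      r = 3, nMales = 96, nFemales = 4))
    expect_equal(round(vc@vmf, 4), row$vmf, label = tr)
  }
  # heritability orientation: published h2/H2 follow from the components
  for (tr in c("panicle_length", "seed_setting_rate")) {
    row <- ref[ref$trait == tr, ]
    vp <- row$vf + row$vm + row$vmf + row$ve
    expect_equal((row$vf + row$vm) / vp, row$h2, tolerance = 5e-4, label = tr)
    expect_equal((row$vf + row$vm + row$vmf) / vp, row$H2, tolerance = 5e-4,
                 label = tr)
  }
})

test_that("equal mean squares give zero genetic components", {
  vc <- varianceComponentsFromMS(5, 5, 5, 5, r = 3, nMales = 10, nFemales = 4)
  expect_equal(c(vc@vm, vc@vf, vc@vmf), c(0, 0, 0))
  expect_equal(vc@h2, 0)
  expect_equal(vc@H2, 0)
})

test_that("negative estimates are flagged raw and truncatable", {
  expect_warning(vc <- varianceComponentsFromMS(1, 1, 5, 2, r = 2,
                                                nMales = 5, nFemales = 3),
                 "negative")
  expect_true(vc@anyNegative)
  expect_lt(vc@vm, 0)
  vt <- varianceComponentsFromMS(1, 1, 5, 2, r = 2, nMales = 5, nFemales = 3,
                                 truncate = TRUE)
  expect_equal(vt@vm, 0)
  expect_true(vt@anyNegative)
})

test_that("method-of-moments estimates are unbiased on synthetic data", {
  ests <- t(vapply(1:60, function(s) {
    cfg <- simConfig(nMales = 12, nFemales = 4, nSnps = 80,
                     nQtlAdditive = 6, nQtlDominance = 4, seed = 900 + s)
    sim <- simulateNCII(cfg)
    vc <- suppressWarnings(varianceComponents(anovaNCII(sim$pheno, sim$design,
                                                        "trait1")))
    tr <- sim$truth
    c(biasVm = vc@vm - sum(tr@trueGcaMales^2) / 11,
      biasVmf = vc@vmf - sum(tr@trueSca^2) / (11 * 3),
      biasVe = vc@ve - cfg$residualSd^2)
  }, c(a = 1, b = 1, c = 1)))
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1])), 2.5 * se[1] + 1e-8)
  expect_lt(abs(mean(ests[, 2])), 2.5 * se[2] + 1e-8)
  expect_lt(abs(mean(ests[, 3])), 2.5 * se[3] + 1e-8)
})

test_that("GCA/SCA decomposition matches hand-computed tables", {
  ca <- computeGcaSca(matrix(c(10, 14, 12, 16), 2, 2,
    dimnames = list(c("m1", "m2"), c("f1", "f2"))))
  expect_equal(grandMean(ca), 13)
  expect_equal(unname(maleGCA(ca)), c(-2, 2))
  expect_equal(unname(femaleGCA(ca)), c(-1, 1))
  expect_equal(max(abs(scaMatrix(ca))), 0)

  pure <- computeGcaSca(matrix(c(10, 14, 14, 10), 2, 2,
    dimnames = list(c("m1", "m2"), c("f1", "f2"))))
  expect_equal(unname(maleGCA(pure)), c(0, 0))
  expect_equal(unname(femaleGCA(pure)), c(0, 0))
  expect_equal(unname(scaMatrix(pure)),
               matrix(c(-2, 2, 2, -2), 2, 2), tolerance = 1e-12)
})

test_that("decomposition reconstructs every cell of a random 4x96 table", {
  set.seed(6)
  cells <- matrix(rnorm(96 * 4, 20, 5), 96, 4,
                  dimnames = list(sprintf("M%02d", 1:96), paste0("F", 1:4)))
  ca <- computeGcaSca(cells)
  recon <- grandMean(ca) + outer(maleGCA(ca), femaleGCA(ca), `+`) +
    scaMatrix(ca)
  expect_equal(unname(recon), unname(cells), tolerance = 1e-12)
  expect_equal(sum(maleGCA(ca)), 0, tolerance = 1e-10)
  expect_equal(sum(femaleGCA(ca)), 0, tolerance = 1e-10)
  expect_equal(max(abs(rowSums(scaMatrix(ca)))), 0, tolerance = 1e-10)
})

test_that("decomposition of noise-free synthetic F1 values equals SimTruth", {
  cfg <- simConfig(nMales = 14, nFemales = 3, nSnps = 90, residualSd = 0,
                   blockSd = 0, seed = 55)
  sim <- simulateNCII(cfg)
  ca <- computeGcaSca(cellMeans(sim$pheno, sim$design, "trait1"))
  expect_equal(unname(maleGCA(ca)), unname(sim$truth@trueGcaMales),
               tolerance = 1e-10)
  expect_equal(unname(scaMatrix(ca)), unname(sim$truth@trueSca),
               tolerance = 1e-10)
})

test_that("missing cells are tolerated with a warning and flagged", {
  cells <- matrix(c(10, 14, NA, 16, 12, 18), 3, 2,
                  dimnames = list(paste0("m", 1:3), paste0("f", 1:2)))
  expect_warning(ca <- computeGcaSca(cells), "approximate")
  expect_false(ca@complete)
})

test_that("heterotic advantage is the percent gain over the male parent", {
  d <- nciiDesign(c("m1", "m2"), "f1")
  ph <- data.frame(id = rep(c("m1", "m2", "m1xf1", "m2xf1"), 2),
                   trait = "t", rep = rep(c("r1", "r2"), each = 4),
                   value = c(20, 20, 30, 20, 20, 20, 30, 20))
  ha <- heteroticAdvantage(ph, d, "t")
  expect_equal(ha$ha[ha$hybrid == "m1xf1"], 50)
  expect_equal(ha$ha[ha$hybrid == "m2xf1"], 0)
  # zero male mean flagged
  ph$value[ph$id == "m2"] <- 0
  ha2 <- heteroticAdvantage(ph, d, "t")
  expect_true(is.na(ha2$ha[ha2$hybrid == "m2xf1"]))
  expect_match(ha2$note[ha2$hybrid == "m2xf1"], "zero")
})

test_that("correlation p-values match the analytic t distribution and cor.test", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7, 2.9)
  y <- c(2.0, 3.1, 2.5, 4.0, 4.9, 1.1, 2.4)
  out <- correlationTests(cbind(a = x), cbind(b = y))
  ct <- cor.test(x, y)
  expect_equal(out$r[1, 1], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(out$p[1, 1], ct$p.value, tolerance = 1e-12)
  # exact linear relation
  out2 <- correlationTests(cbind(x = x), cbind(y = 2 * x + 1))
  expect_equal(out2$r[1, 1], 1)
  expect_equal(out2$p[1, 1], 0)
  # zero-variance column undefined
  out3 <- correlationTests(cbind(x = x), cbind(z = rep(1, 7)))
  expect_true(is.na(out3$r[1, 1]))
})

test_that("null correlations are small and p roughly uniform at n = 1000", {
  set.seed(77)
  ps <- replicate(40, {
    x <- rnorm(1000); y <- rnorm(1000)
    out <- correlationTests(cbind(x), cbind(y))
    c(out$r[1, 1], out$p[1, 1])
  })
  expect_true(all(abs(ps[1, ]) < 0.1))
  expect_gt(ks.test(ps[2, ], "punif")$p.value, 0.01)
})
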