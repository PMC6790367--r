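#' NCII two-factor analysis of variance
#'
#' Classical balanced two-factor ANOVA with replication for a North
#' Carolina design II: strata for replications, males, females, the
#' male x female interaction, and error. Under the random-effects NCII
#' convention the F statistics for males and females use the interaction
#' mean square as denominator, while the interaction and replications
#' are tested against the error mean square. Significance stars follow
#' the usual field-trial convention: `**` P < 0.01, `***` P < 0.001,
#' `****` P < 0.0001.
#'
#' The expected-mean-squares pathway requires a balanced design: every
#' male x female cell observed in every replication, exactly once.
#' Unbalanced input is rejected with a pointer to the cell-mean GCA/SCA
#' route ([computeGcaSca()]), which needs no EMS algebra.
#'
#' @param pheno long phenotype data.frame (`id`, `trait`, `rep`,
#'   `value`), ids matching the design's hybrid ids.
#' @param design an [NCIIDesign-class].
#' @param trait trait to analyse.
#' @return An [AnovaTable-class].
#' @export
anovaNCII <- function(pheno, design, trait) {
  stopifnot(is(design, "NCIIDesign"))
  validatePhenotypes(pheno)
  ph <- pheno[pheno$trait == trait & pheno$id %in% crossMap(design)$hybrid, ]
  if (!nrow(ph)) stop("no phenotype records for trait '", trait, "'")
  cr <- crossMap(design)
  f <- length(maleIds(design))      # number of male parents
  m <- length(femaleIds(design))    # number of female parents
  reps <- sort(unique(ph$rep))
  r <- length(reps)
  if (f < 2 || m < 2 || r < 2)
    stop("need >= 2 males, >= 2 females and >= 2 replications")

  idx <- match(ph$id, cr$hybrid)
  male <- factor(cr$male[idx], maleIds(design))
  female <- factor(cr$female[idx], femaleIds(design))
  rep_ <- factor(ph$rep, reps)
  counts <- table(male, female, rep_)
  if (any(counts != 1L) || anyNA(ph$value))
    stop("unbalanced or incomplete data: the EMS pathway needs every ",
         "cross in every replication exactly once; use computeGcaSca() ",
         "on cell means for unbalanced designs")

  y <- ph$value
  grand <- mean(y)
  mMale <- tapply(y, male, mean)
  mFem <- tapply(y, female, mean)
  mRep <- tapply(y, rep_, mean)
  mCell <- tapply(y, list(male, female), mean)

  ssRep <- m * f * sum((mRep - grand)^2)
  ssM <- r * m * sum((mMale - grand)^2)
  ssF <- r * f * sum((mFem - grand)^2)
  ssMF <- r * sum((sweep(sweep(mCell - grand, 1, mMale - grand), 2,
                         mFem - grand))^2)
  ssTot <- sum((y - grand)^2)
  ssErr <- max(ssTot - ssRep - ssM - ssF - ssMF, 0)

  df <- c(r - 1, f - 1, m - 1, (f - 1) * (m - 1), (r - 1) * (m * f - 1))
  ss <- c(ssRep, ssM, ssF, ssMF, ssErr)
  ms <- ss / df
  msMF <- ms[4]; msE <- ms[5]
  fstat <- c(if (msE > 0) ms[1] / msE else NA_real_,
             if (msMF > 0) ms[2] / msMF else NA_real_,
             if (msMF > 0) ms[3] / msMF else NA_real_,
             if (msE > 0) ms[4] / msE else NA_real_,
             NA_real_)
  dfDen <- c(df[5], df[4], df[4], df[5], NA)
  p <- ifelse(is.na(fstat), NA_real_,
              stats::pf(fstat, df, dfDen, lower.tail = FALSE))
  sig <- vapply(p, .sigStars, "")
  tab <- data.frame(
    source = c("Replications", "Males", "Females", "Males x Females", "Error"),
    df = df, ss = ss, ms = ms, fstat = fstat, p = p, sig = sig,
    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(source = "Total", df = r * m * f - 1,
                               ss = ssTot, ms = NA, fstat = NA, p = NA,
                               sig = "", stringsAsFactors = FALSE))
  new("AnovaTable", table = tab, r = as.integer(r), nMales = as.integer(f),
      nFemales = as.integer(m), trait = as.character(trait))
}

.sigStars <- function(p) {
  if (is.na(p)) "" else if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 0.01) "**" else ""
}

#' @describeIn anovaNCII the ANOVA data.frame
#' @param x an `AnovaTable`
#' @export
anovaTable <- function(x) x@table

#' @export
setMethod("show", "AnovaTable", function(object) {
  cat("NCII ANOVA, trait:", object@trait, "(", object@nMales, "males x",
      object@nFemales, "females,", object@r, "reps )\n")
  print(object@table, row.names = FALSE, digits = 5)
})

#' Method-of-moments NCII variance components and heritabilities
#'
#' Solves the NCII expected mean squares for the variance components:
#' female additive \eqn{\sigma_f^2 = (MS_F - MS_{MF}) / (r f)}, male
#' additive \eqn{\sigma_m^2 = (MS_M - MS_{MF}) / (r m)}, nonadditive
#' \eqn{\sigma_{mf}^2 = (MS_{MF} - MS_e) / r}, error
#' \eqn{\sigma_e^2 = MS_e}, with f the number of males, m the number of
#' females and r the replications — each parental component is divided
#' by r times the size of the opposite parent group, the textbook
#' balanced-design coefficients (exposed in the `divisors` slot).
#' Heritabilities are \eqn{h^2 = (\sigma_f^2 + \sigma_m^2) / \sigma_P^2}
#' (narrow sense, additive over phenotypic) and
#' \eqn{H^2 = \sigma_G^2 / \sigma_P^2} (broad sense).
#'
#' Negative method-of-moments estimates are reported as computed with
#' the `anyNegative` flag set; `truncate = TRUE` clamps them at zero
#' before forming ratios.
#'
#' @param x an [AnovaTable-class], or the male mean square `MS1` when
#'   calling [varianceComponentsFromMS()] directly.
#' @param truncate clamp negative component estimates at zero.
#' @return A [VarianceComponents-class].
#' @export
varianceComponents <- function(x, truncate = FALSE) {
  stopifnot(is(x, "AnovaTable"))
  tab <- x@table
  ms <- stats::setNames(tab$ms, tab$source)
  varianceComponentsFromMS(ms[["Males"]], ms[["Females"]],
                           ms[["Males x Females"]], ms[["Error"]],
                           r = x@r, nMales = x@nMales, nFemales = x@nFemales,
                           truncate = truncate, trait = x@trait)
}

#' @rdname varianceComponents
#' @param ms1 male mean square; @param ms2 female mean square;
#' @param ms3 male x female interaction mean square;
#' @param msError error mean square.
#' @param r replications; @param nMales,nFemales factorial dimensions.
#' @param trait trait label.
#' @examples
#' # interaction component from printed mean squares:
#' vc <- varianceComponentsFromMS(1923, 10226, 453, 105,
#'                                r = 3, nMales = 96, nFemales = 4)
#' vc@vmf   # (453 - 105) / 3 = 116
#' @export
varianceComponentsFromMS <- function(ms1, ms2, ms3, msError, r,
                                     nMales, nFemales, truncate = FALSE,
                                     trait = NA_character_) {
  if (missing(r) || missing(nMales) || missing(nFemales))
    stop("r, nMales and nFemales are required")
  divisors <- c(vm = r * nFemales, vf = r * nMales, vmf = r)
  vm <- (ms1 - ms3) / divisors[["vm"]]
  vf <- (ms2 - ms3) / divisors[["vf"]]
  vmf <- (ms3 - msError) / divisors[["vmf"]]
  ve <- msError
  anyNeg <- any(c(vm, vf, vmf, ve) < 0)
  if (anyNeg && !truncate)
    warning("negative variance component estimate(s); see truncate = TRUE")
  if (truncate) {
    vm <- max(vm, 0); vf <- max(vf, 0); vmf <- max(vmf, 0); ve <- max(ve, 0)
  }
  vg <- vf + vm + vmf
  vp <- vg + ve
  h2 <- if (vp > 0) (vf + vm) / vp else 0
  H2 <- if (vp > 0) vg / vp else 0
  new("VarianceComponents", vf = vf, vm = vm, vmf = vmf, ve = ve,
      vg = vg, vp = vp, h2 = h2, H2 = H2,
      anyNegative = anyNeg, truncated = truncate,
      divisors = divisors, trait = trait)
}

#' @export
setMethod("show", "VarianceComponents", function(object) {
  cat("NCII variance components",
      if (!is.na(object@trait)) paste0("(", object@trait, ")"), "\n")
  cat(sprintf("  male %.4f | female %.4f | male x female %.4f | error %.4f\n",
              object@vm, object@vf, object@vmf, object@ve))
  cat(sprintf("  h2 = %.4f, H2 = %.4f%s\n", object@h2, object@H2,
              if (object@anyNegative) "  [negative estimate(s) flagged]" else ""))
})
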