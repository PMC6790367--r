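#' Male x female cell means for one trait
#'
#' Averages replicate observations of each hybrid and arranges them as a
#' males x females matrix in design order. Missing crosses give `NA`
#' cells.
#'
#' @param pheno long phenotype data.frame.
#' @param design an [NCIIDesign-class].
#' @param trait trait name.
#' @return numeric matrix, males in rows, females in columns.
#' @export
cellMeans <- function(pheno, design, trait) {
  tm <- traitMatrix(pheno[pheno$trait == trait, , drop = FALSE])
  cr <- crossMap(design)
  vals <- tm[match(cr$hybrid, rownames(tm)), trait]
  out <- matrix(NA_real_, length(maleIds(design)), length(femaleIds(design)),
                dimnames = list(maleIds(design), femaleIds(design)))
  out[cbind(match(cr$male, maleIds(design)),
            match(cr$female, femaleIds(design)))] <- vals
  out
}

#' GCA/SCA decomposition of a cell-mean table
#'
#' Decomposes the male x female table of cross means Y_ij into the grand
#' mean Y, general combining abilities G_i = Y_i - Y (male margins) and
#' G_j = Y_j - Y (female margins), and specific combining abilities
#' S_ij = Y_ij - Y_i - Y_j + Y, so that Y + G_i + G_j + S_ij
#' reconstructs every cell exactly for complete tables. Margins are
#' unweighted means of the available cells; with missing cells the
#' zero-sum identities hold only approximately and the `complete` slot
#' is set to `FALSE` with a warning.
#'
#' @param cells males x females numeric matrix of cross means (rownames
#'   male ids, colnames female ids), e.g. from [cellMeans()].
#' @param trait optional trait label.
#' @return A [CombiningAbility-class].
#' @examples
#' ca <- computeGcaSca(matrix(c(10, 14, 12, 16), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("f1", "f2"))))
#' maleGCA(ca)   # -2, +2
#' @export
computeGcaSca <- function(cells, trait = NA_character_) {
  cells <- as.matrix(cells)
  if (any(rowSums(!is.na(cells)) == 0) || any(colSums(!is.na(cells)) == 0))
    stop("cell-mean table has fully missing row(s) or column(s)")
  complete <- !anyNA(cells)
  grand <- mean(cells, na.rm = TRUE)
  gi <- rowMeans(cells, na.rm = TRUE) - grand
  gj <- colMeans(cells, na.rm = TRUE) - grand
  sca <- sweep(sweep(cells - grand, 1, gi), 2, gj)
  if (!complete)
    warning("missing cells: zero-sum identities are approximate")
  if (is.null(rownames(cells))) rownames(sca) <- names(gi) <-
      paste0("male", seq_len(nrow(cells)))
  if (is.null(colnames(cells))) colnames(sca) <- names(gj) <-
      paste0("female", seq_len(ncol(cells)))
  new("CombiningAbility", grandMean = grand,
      maleGCA = stats::setNames(gi, rownames(sca)),
      femaleGCA = stats::setNames(gj, colnames(sca)),
      sca = sca, cellMeans = cells, complete = complete,
      trait = as.character(trait))
}

#' @describeIn computeGcaSca male GCA vector
#' @param x a `CombiningAbility`
#' @export
maleGCA <- function(x) x@maleGCA

#' @describeIn computeGcaSca female GCA vector
#' @export
femaleGCA <- function(x) x@femaleGCA

#' @describeIn computeGcaSca SCA matrix (males x females)
#' @export
scaMatrix <- function(x) x@sca

#' @describeIn computeGcaSca grand mean of the cell table
#' @export
grandMean <- function(x) x@grandMean

#' @describeIn computeGcaSca per-hybrid SCA as a named vector, in the
#'   order of a design's cross map
#' @param design an [NCIIDesign-class]
#' @export
scaByHybrid <- function(x, design) {
  cr <- crossMap(design)
  stats::setNames(x@sca[cbind(match(cr$male, rownames(x@sca)),
                              match(cr$female, colnames(x@sca)))],
                  cr$hybrid)
}

#' @export
setMethod("show", "CombiningAbility", function(object) {
  cat("CombiningAbility:", nrow(object@sca), "males x", ncol(object@sca),
      "females | grand mean", sprintf("%.4g", object@grandMean),
      if (!object@complete) "| INCOMPLETE cells", "\n")
  cat("  male GCA range:", sprintf("%.4g", range(object@maleGCA)), "\n")
})

#' Heterotic advantage of hybrids over their male parents
#'
#' Heterotic advantage is the percentage difference between a hybrid and
#' its male parent, HA = 100 (hybrid - male) / male — the male-parent
#' reference is used because female testers are male-sterile and their
#' own trait values cannot be measured. Trait values are replicate means.
#'
#' @param pheno long phenotype data.frame containing both hybrid and
#'   male-parent records.
#' @param design an [NCIIDesign-class].
#' @param trait trait name.
#' @return data.frame with columns `hybrid`, `male`, `female`,
#'   `maleValue`, `hybridValue`, `ha` (percent; `NA` with `note` set
#'   when the male mean is missing or zero).
#' @export
heteroticAdvantage <- function(pheno, design, trait) {
  tm <- traitMatrix(pheno[pheno$trait == trait, , drop = FALSE])
  cr <- crossMap(design)
  maleVal <- tm[match(cr$male, rownames(tm)), trait]
  hybVal <- tm[match(cr$hybrid, rownames(tm)), trait]
  ha <- ifelse(!is.na(maleVal) & maleVal != 0,
               100 * (hybVal - maleVal) / maleVal, NA_real_)
  note <- rep("", nrow(cr))
  note[is.na(maleVal)] <- "male parent value missing"
  note[!is.na(maleVal) & maleVal == 0] <- "male parent mean is zero"
  data.frame(hybrid = cr$hybrid, male = cr$male, female = cr$female,
             maleValue = maleVal, hybridValue = hybVal, ha = ha,
             note = note, stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise Pearson correlations with two-sided t tests
#'
#' Correlations are computed on pairwise-complete observations; the
#' p-value of each coefficient comes from the two-sided t test
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' Zero-variance columns yield `NA`.
#'
#' @param X id x trait numeric matrix (e.g. from [traitMatrix()]).
#' @param Y optional second matrix with the same rows; default
#'   correlates the columns of `X` with each other.
#' @return list with matrices `r`, `p` and `n` (pairs used).
#' @export
correlationTests <- function(X, Y = NULL) {
  X <- as.matrix(X)
  Y2 <- if (is.null(Y)) X else as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y2))
  r <- matrix(NA_real_, ncol(X), ncol(Y2),
              dimnames = list(colnames(X), colnames(Y2)))
  p <- r; n <- r
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Y2))) {
    ok <- stats::complete.cases(X[, i], Y2[, j])
    nij <- sum(ok)
    n[i, j] <- nij
    if (nij < 3) next
    xi <- X[ok, i]; yj <- Y2[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(yj) == 0) next
    rij <- stats::cor(xi, yj)
    r[i, j] <- rij
    if (abs(rij) >= 1) { p[i, j] <- 0; next }
    tt <- rij * sqrt((nij - 2) / (1 - rij^2))
    p[i, j] <- 2 * stats::pt(-abs(tt), nij - 2)
  }
  list(r = r, p = p, n = n)
}
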