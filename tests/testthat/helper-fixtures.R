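# Small fixtures built in code; all randomness is locally seeded.

toyGenotype <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("s%02d", seq_len(nrow(codes)))
  n <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq(100L, by = 1000L, length.out = n)
  GenotypeMatrix(codes, data.frame(chrom = chrom, pos = pos,
                                   ref = rep("A", n), alt = rep("G", n),
                                   stringsAsFactors = FALSE))
}

randomGenotype <- function(n, m, maf = 0.3, missingProb = 0, seed = 1,
                           inbred = FALSE) {
  set.seed(seed)
  if (inbred) {
    codes <- matrix(2L * rbinom(n * m, 1, maf), n, m)
  } else {
    codes <- matrix(rbinom(n * m, 2, maf), n, m)
  }
  if (missingProb > 0)
    codes[runif(n * m) < missingProb] <- NA_integer_
  rownames(codes) <- sprintf("s%03d", seq_len(n))
  toyGenotype(codes)
}

# balanced 2 males x 2 females x 2 reps toy with known cell values
toy222Pheno <- function() {
  design <- nciiDesign(c("m1", "m2"), c("f1", "f2"),
                       repLabels = c("r1", "r2"))
  vals <- rbind(
    c("m1xf1", 10, 12), c("m1xf2", 14, 16),
    c("m2xf1", 20, 22), c("m2xf2", 24, 26))
  pheno <- data.frame(
    id = rep(vals[, 1], 2), trait = "t",
    rep = rep(c("r1", "r2"), each = 4),
    value = as.numeric(c(vals[, 2], vals[, 3])),
    stringsAsFactors = FALSE)
  list(design = design, pheno = pheno)
}

# direct (oracle) sums of squares for a balanced two-factor design with
# a replications stratum, computed by explicit enumeration over groups
bruteForceSS <- function(pheno, design, trait) {
  cr <- crossMap(design)
  ph <- pheno[pheno$trait == trait, ]
  idx <- match(ph$id, cr$hybrid)
  male <- cr$male[idx]; female <- cr$female[idx]
  y <- ph$value
  grand <- mean(y)
  ssOf <- function(groups) {
    sum(vapply(unique(groups), function(g) {
      length(y[groups == g]) * (mean(y[groups == g]) - grand)^2
    }, 1))
  }
  ssM <- ssOf(male); ssF <- ssOf(female); ssRep <- ssOf(ph$rep)
  cellKey <- paste(male, female)
  ssCells <- ssOf(cellKey)
  ssMF <- ssCells - ssM - ssF
  ssTot <- sum((y - grand)^2)
  list(rep = ssRep, males = ssM, females = ssF, mf = ssMF,
       error = ssTot - ssRep - ssCells, total = ssTot)
}

# write a small VCF with given GT strings (variants x samples)
writeToyVCF <- function(path, gt, chrom, pos, ref, alt,
                        samples = paste0("s", seq_len(ncol(gt)))) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(gt)), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  path
}
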