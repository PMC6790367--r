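---
title: "Combining-ability analysis and mixed-model GWAS for NCII mating designs"
author: "NCIIgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining-ability analysis and mixed-model GWAS for NCII mating designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NCIIgwas)
```

## The design and the model

A North Carolina design II (NCII) crosses every line in a male panel with
every line in a small set of female testers and evaluates the hybrids in a
replicated field trial. In two-line hybrid rice the female testers are
photo-thermo-sensitive male-sterile lines, so the design is the workhorse
for choosing parents: a parent's *general combining ability* (GCA) is the
deviation of its hybrids' mean from the grand mean, and the *specific
combining ability* (SCA) of a cross is what its parents' GCAs do not
predict,

$$Y_{ij} = Y + G_i + G_j + S_{ij},$$

with $G_i = Y_i - Y$, $G_j = Y_j - Y$ and $S_{ij} = Y_{ij} - Y_i - Y_j + Y$
(cell means; the `+Y` sign is forced by the decomposition model). GCA
reflects additive gene action, SCA nonadditive gene action. For complete
tables the GCA vectors and every SCA margin sum to zero exactly, and the
four terms reconstruct each cell — `computeGcaSca()` treats these
identities as testable contracts.

## ANOVA, variance components, heritability

`anovaNCII()` fits the balanced two-factor ANOVA with a replications
stratum. With $f$ males, $m$ females and $r$ replications, the expected
mean squares give the method-of-moments components implemented in
`varianceComponents()`:

$$\sigma_m^2 = \frac{MS_M - MS_{MF}}{r\,m}, \quad
  \sigma_f^2 = \frac{MS_F - MS_{MF}}{r\,f}, \quad
  \sigma_{mf}^2 = \frac{MS_{MF} - MS_e}{r}, \quad
  \sigma_e^2 = MS_e,$$

i.e. each parental component is divided by $r$ times the size of the
*opposite* parent group — the textbook balanced coefficients, exposed in
the result's `divisors` slot for transparency. Heritabilities are

$$h^2 = \frac{\sigma_m^2 + \sigma_f^2}{\sigma_P^2}, \qquad
  H^2 = \frac{\sigma_m^2 + \sigma_f^2 + \sigma_{mf}^2}{\sigma_P^2},$$

narrow sense as additive over phenotypic and broad sense as total genetic
over phenotypic. Published NCII tables sometimes swap the two labels in
their equation listings; we verified this orientation numerically against
the worked examples shipped in `riceAnovaReference()` (e.g. panicle
length: $(2.2923 + 1.3099)/5.6546 = 0.6370$ is the printed narrow-sense
value) and use it throughout.

Main-effect F statistics are tested against the interaction mean square
and the interaction against the error mean square, the random-effects NCII
convention. Negative method-of-moments estimates are reported as computed
with a flag — truncation at zero is available but not silent, so that
unbiasedness checks on simulations remain meaningful. Unbalanced data are
rejected by the EMS pathway and routed to the cell-mean GCA/SCA
decomposition, which needs no EMS algebra; REML components for unbalanced
designs are out of scope.

```{r}
vc <- varianceComponentsFromMS(1923, 10226, 453, 105,
                               r = 3, nMales = 96, nFemales = 4)
vc
```

## The Q+K association model

`gwasPipeline()` scans traits, GCA or SCA with the mixed model
$y = X\beta + x_j b_j + u + e$, $u \sim N(0, \sigma_g^2 K)$,
$e \sim N(0, \sigma_e^2 I)$, where $X$ holds an intercept and the top
five principal components of the genotype matrix (structure, "Q") and $K$
is the identity-by-state kinship — the proportion of shared SNP alleles,
$(2 - |g_s - g_t|)/2$ averaged over loci. Variance components are
estimated once under the null by REML — the likelihood is profiled onto
$\delta = \sigma_e^2/\sigma_g^2$, optimized on a 100-point grid over
$\log\delta \in [-10, 10]$ and refined by golden-section search to
$10^{-6}$ — and then every variant is tested by generalized least squares
with the covariance held fixed, the EMMAX approximation. The per-variant
statistic is $t = \hat b/\mathrm{se}(\hat b)$ on $n - \mathrm{rank}(X) - 1$
degrees of freedom (the reference program's choice is undocumented; this
is the GLS-natural one). An exact mode that refits REML per variant is
provided for small-instance cross-validation; with $\sigma_g^2 = 0$ the
scan reduces to weighted OLS exactly, which the tests exploit as an
oracle.

Three genotype encodings cover additive and non-additive gene action:
additive leaves dosages 0/1/2 unchanged; *dominant* recodes heterozygotes
as alt homozygotes (1 → 2); *recessive* recodes them as ref homozygotes
(1 → 0). SCA is dominated by non-additive action, so its scans are run
under the dominant/recessive encodings — on additive dosages a
pure-dominance locus at intermediate frequency is nearly orthogonal to
the SCA signal, and the acceptance tests reproduce exactly this contrast.

GCA scans use male-parent genotypes with each parent's GCA as its trait
value; only the male panel is scanned because a handful of female testers
carries no mappable variation (the female margin is absorbed). SCA scans
use the F1 genotypes, which are derived deterministically from the inbred
parents (`deriveF1Genotypes()`); a switch allows scanning F1 targets on
male-parent genotypes instead, since with inbred parents either choice is
defensible.

### Significance threshold

`effectiveSnpCount()` replaces the Bonferroni $M$ with the effective
number of independent tests $M_e$, computed per non-overlapping window of
consecutive variants (default 1000) from the eigenvalues $\lambda_i$ of
the variant correlation matrix as
$\sum_i \big(\mathbf{1}[\lambda_i \ge 1] + (\lambda_i -
\lfloor\lambda_i\rfloor)\big)$ — the Li–Ji-family effective-count rule.
The genome-wide threshold is $0.05/M_e$. $M_e$ depends on the genotype
panel, so thresholds from other datasets are not comparable; with our
synthetic panels (mostly loose LD) $M_e/M$ is close to 1 and the threshold
close to plain Bonferroni.

## The synthetic NCII generator

`simulateNCII()` generates the data the analysis assumes, with exact
ground truth, emulating a rice NCII trial: by default 96 inbred males in
3 subpopulations, 4 inbred female testers, the full 384-cross factorial
and 3 replications. Choices worth knowing:

* **Structure** follows a Balding–Nichols model: ancestral frequency
  $p \sim U(\mathrm{mafRange})$ per SNP, subpopulation frequencies
  $\mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$. The default
  $F_{ST} = 0.2$ makes the subpopulations cleanly separable on PC1,
  matching the strong *indica*–*japonica*-style differentiation such
  panels show; the source describes its structure only phenomenologically,
  so this is the simplest generative model with the required property.
  Females all come from subpopulation 1, mirroring testers drawn from a
  single group.
* **Parents are fully inbred** (codes 0/2 only), as rice inbred lines
  are; this makes F1 genotypes deterministic and needs no linkage model —
  a single meiosis from an inbred parent transmits its only haplotype.
  There is consequently **no distance-dependent LD decay** in simulated
  chromosomes: within-chromosome LD comes from structure (and in F1s from
  the female-block crossing pattern) and is flat in distance. Ordering
  statements (F1 LD exceeds parental LD) are meaningful; absolute decay
  distances in kb are not, and real-data decay scales cannot be
  reproduced here.
* **Genetic values** are $\sum_k a_k x_k + \sum_k d_k \mathbf{1}[x_k = 1]$:
  additive QTLs ($a_k \sim N(0, sd)$) and dominance QTLs (effect on
  heterozygotes only) at distinct loci. The dominance indicator is the
  minimal model consistent with a $d/a$ analysis; epistasis, G×E and
  sterility loci are deliberately absent. Explicit planted architectures
  (`qtl`, `aEffects`, `dEffects`) support validation experiments.
* **Observed values** add a grand mean (10), one block effect per
  replicate shared by all entries (randomized-block layout), and Gaussian
  residuals. Block variance sits in the replications stratum, so it does
  not enter the phenotypic variance used for heritability.
* **Ground truth**: the noise-free F1 genetic values are decomposed cell
  by cell into GCA/SCA, and realized heritabilities use sample variances
  of those effects with $n-1$ denominators plus $\sigma_e^2$ — exactly
  the quantities the method-of-moments estimators target, which is what
  makes recovery experiments well-posed.
* **Reproducibility**: one seed per dataset, split into named sub-streams
  (`parents`, `phenotypes`), so stages are individually reproducible and
  identical configs give bit-identical outputs.

What passing tests on these data show — and what they do not: the
generator reproduces the *statistical* structure the methods assume
(balanced factorial, inbred parents, additive + dominance architecture,
population structure). It does not emulate linkage, allele-frequency
spectra after domestication, G×E, or measurement artefacts, so green
tests certify the machinery, not field performance on real panels.

## Numerical and design choices

* Problem sizes in tests and the acceptance script were chosen so the
  whole suite exercises the full 96 × 4 × 3 design where the claim is
  about that scale (heritability recovery, planted-signal scans) and
  smaller factorials elsewhere; simulations use 150–2000 SNPs, enough for
  the structure/kinship machinery without inflating runtimes.
* Heritability-recovery experiments use an architecture calibrated to a
  realized $h^2 \approx 0.6$ (30 additive QTLs of sd 0.40, 10 dominance
  QTLs of sd 0.15, residual sd 1), the mid-range of the heritabilities
  such trials report (~0.13–0.76 across yield traits).
* Planted dominance QTLs for the SCA-scan experiments are placed at loci
  segregating at intermediate frequency in the male panel *and*
  polymorphic among the four females: if all testers are identical at a
  locus, heterozygosity is a male-margin function and SCA absorbs it —
  a real identifiability limit of the design, not an implementation one.
* Missing genotype calls are mean-imputed within a tested variant (MAF is
  computed before imputation); monomorphic or covariate-collinear
  variants are reported with a reason, never silently dropped.
* Variant filtering uses MAF ≥ threshold and missing rate strictly below
  threshold (a variant at exactly 15% missingness is removed). Filtering
  is applied to whatever matrix the caller provides; whether hybrids
  should be re-filtered after deriving F1s is left to the caller and
  defaults to the parental filter only.
* PCA is raw SVD of the column-centred dosage matrix — no unit-variance
  scaling — restricted to complete variants; component signs are fixed by
  orienting the largest-magnitude loading positive.
* LD $r^2$ is the squared correlation of dosages, which coincides with
  haplotype $r^2$ for fully homozygous panels; for heterozygous panels
  the two differ and only the dosage version is implemented.
* The dominance index reports both the population-mean form
  $d = \bar y_{het} - \bar y$ (frequency-dependent, used as the headline
  for comparability with published NCII GWAS practice) and the classical
  midpoint form $d = \bar y_{het} - (\bar y_{rr} + \bar y_{aa})/2$;
  $a$ is half the homozygote contrast. $|d/a| > 1$ flags overdominance.
* Favourable alleles for `alleleAccumulation()` are declared by the
  caller (typically from scan effect signs) rather than inferred
  silently.

## Known limitations

Unbalanced designs get the cell-mean decomposition only (no REML
components); the generator has no linkage map, so LD-decay *distances*
are not meaningful; the effective-test count depends on windowing and is
not comparable across datasets; per-variant REML ("exact" mode) is
quadratic-in-variants slow by design and intended for cross-validation
only.

## A worked run

```{r}
sim <- simulateNCII(simConfig(nMales = 24, nFemales = 4, nSnps = 300,
                              seed = 11))
av <- anovaNCII(sim$pheno, sim$design, "trait1")
varianceComponents(av)
ca <- computeGcaSca(cellMeans(sim$pheno, sim$design, "trait1"))
ca
head(heteroticAdvantage(sim$pheno, sim$design, "trait1")[, c("hybrid", "ha")])
```
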