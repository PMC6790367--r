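Package: NCIIgwas
Title: Combining-Ability Analysis and Mixed-Model GWAS for North Carolina
    II Mating Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative-genetic analysis of North Carolina design II
    (NCII) factorial mating experiments in inbred crops such as rice.
    Implements the balanced two-factor ANOVA with a replications stratum,
    method-of-moments variance components and narrow-/broad-sense
    heritability, general and specific combining ability (GCA/SCA)
    decomposition, heterotic advantage, and EMMAX-style Q+K linear
    mixed-model association scans of traits, GCA and SCA under additive,
    dominant and recessive genotype encodings with an effective-number-
    of-tests significance threshold. Includes population-structure and
    linkage-disequilibrium summaries, per-locus effect characterization
    (dominance index d/a, variance explained, favourable-allele
    accumulation), and a synthetic NCII data generator with known ground
    truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
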