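#' Published rice NCII trial ANOVA summary
#'
#' Mean squares and derived variance components for 12 yield-related
#' traits from a published rice North Carolina II field trial (96 male x
#' 4 female inbred parents, 3 replications), shipped as plain text in
#' `inst/extdata/rice_ncii_anova_ms.tsv`. Columns: `ms_males`,
#' `ms_females`, `ms_mf` (interaction), `ms_rep` (replications), the
#' published components `vf` (female additive), `vm` (male additive),
#' `vmf` (nonadditive), `ve` (error = error mean square), and `h2`/`H2`.
#' Mean squares larger than 100 were rounded to whole numbers in the
#' source, which limits the precision of components recomputed from
#' them.
#'
#' These printed mean squares are inputs for worked examples of
#' [varianceComponentsFromMS()]: the published components and
#' heritabilities are reproduced from them with `r = 3`, `nMales = 96`,
#' `nFemales = 4`.
#'
#' @return data.frame, one row per trait.
#' @examples
#' ref <- riceAnovaReference()
#' row <- ref[ref$trait == "heading_date", ]
#' varianceComponentsFromMS(row$ms_males, row$ms_females, row$ms_mf,
#'                          row$ve, r = 3, nMales = 96, nFemales = 4)
#' @export
riceAnovaReference <- function() {
  utils::read.table(system.file("extdata", "rice_ncii_anova_ms.tsv",
                                package = "NCIIgwas"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
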