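#' Published PB92 single-mutant measurement table
#'
#' Measurements for wild-type subtilisin PB92 and its 21 single-point mutants
#' as printed in a published thermostability-engineering study: relative
#' extracellular activity (% of wild type), optimal temperature (deg C, `NA`
#' where activity was too low to characterize), half-life at 65 deg C (min),
#' plus the study's reported fold-increase and activity/thermostability/
#' composite scores for cross-checking recomputations. These are wet-lab
#' measurements and enter the pipeline only as inputs; every derived quantity
#' (scores, folds, plans) is recomputed by this package.
#'
#' Known printing inconsistencies in the source (kept verbatim in the
#' `*_reported` columns): the G98E and G100E reported thermostability scores
#' are decimal-shifted relative to their own composite scores; the R143G
#' half-life and fold-increase are mutually inconsistent; the S101G reported
#' activity score (94.23) differs from its measured relative activity
#' (90.29, used here).
#'
#' @return Data.frame with columns `mutant_id`, `rel_activity_pct`, `topt_C`,
#'   `t_half_min`, `fold_increase_reported`, `thermo_score_reported`,
#'   `activity_score_reported`, `composite_score_reported`.
#' @examples
#' head(pb92_single_mutants())
#' @export
pb92_single_mutants <- function() {
  read_tsv(system.file("extdata", "pb92_single_mutants.tsv",
                       package = "thermorank", mustWork = TRUE))
}

#' Published PB92 combination-mutant measurement table
#'
#' Half-lives at 65 deg C and reported composite scores for the wild type and
#' the six combination mutants built on the N18L/R143L base with additions
#' from the S97-G100 loop.
#'
#' @return Data.frame with columns `mutant_id`, `substitutions`,
#'   `t_half_min`, `fold_increase_reported`, `composite_score_reported`.
#' @examples
#' pb92_complex_mutants()
#' @export
pb92_complex_mutants <- function() {
  read_tsv(system.file("extdata", "pb92_complex_mutants.tsv",
                       package = "thermorank", mustWork = TRUE))
}
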