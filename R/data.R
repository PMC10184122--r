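#' Literature per-bond rupture free energies for CRBN--CK1alpha complexes
#'
#' Reported hydrogen-bond rupture free-energy endpoints (kcal/mol, with
#' bootstrap errors) for the three interfacial H-bonds of the
#' CRBN--CK1alpha system: the wild-type ternary complex with lenalidomide
#' (`wt_LEN`), the binary complex without the glue (`wt_noLEN`), and the
#' I35G, I37E, N39G and G40N CK1alpha point mutants (all with
#' lenalidomide). Bond labels follow the CRBN-side-chain --
#' CK1alpha-carbonyl convention (`W400-N39`, `H357-T38`, `N351-I37`).
#'
#' @return A tibble with columns `complex`, `bond`, `pmf`, `sd`.
#' @seealso [ck1a_reference_totals()] for the corresponding published
#'   per-complex totals.
#' @export
ck1a_reference_endpoints <- function() {
  path <- system.file("extdata", "ck1a_pmf_reference.tsv",
                      package = "glueforce", mustWork = TRUE)
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  .check_records(out)
  out
}

#' Published per-complex rupture totals for CRBN--CK1alpha complexes
#'
#' The per-complex sums of the three per-bond rupture free energies as
#' printed in the source report. Three of the six printed totals
#' (`wt_noLEN`, `N39G`, `G40N`) disagree with the sum of their own
#' printed components at one decimal; [build_energetics_table()] flags
#' these rather than correcting either side.
#'
#' @return A tibble with columns `complex`, `total`, `error`.
#' @export
ck1a_reference_totals <- function() {
  path <- system.file("extdata", "ck1a_pmf_printed_totals.tsv",
                      package = "glueforce", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
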