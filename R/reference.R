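#' Bundled reference screen of five asthma biologics
#'
#' Summary statistics from a large-scale global spontaneous-report screen of
#' asthma biologics (omalizumab, mepolizumab, benralizumab, reslizumab,
#' dupilumab) against the narrow anaphylactic-reaction query: per drug-PT
#' pair, the report count, its share of the drug's total, and the published
#' PRR, ROR and IC025, with the published signal flag. Bundled as an
#' internal-consistency fixture: the ratio estimators can be cross-checked
#' against these rows (e.g. via [ror_from_prr()]) without access to the
#' underlying restricted database. Note the published PT list includes
#' "anaphylactoid shock" and "shock symptom", which are not part of the
#' bundled narrow query definition.
#'
#' @return tibble `drug`, `drug_total`, `pt_term`, `n`, `prr`, `ror`,
#'   `ic025`, `signal_flagged`.
#' @export
reference_screen <- function() {
  path <- system.file("extdata", "reference_screen.csv", package = "pvsignal",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "cicidddl", progress = FALSE)
}

#' Bundled reference headline counts
#'
#' Numerator/denominator pairs for the headline proportions of the same
#' reference screen as [reference_screen()]: the biologics' share of the
#' full database, the case share among biologic reports, the serious shares,
#' and the omalizumab anaphylactic-reaction reporting share.
#'
#' @return tibble `quantity`, `numerator`, `denominator`.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_counts.csv", package = "pvsignal",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "cii", progress = FALSE)
}
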