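#' Published reference tables for arithmetic-consistency validation
#'
#' The package ships three small reference tables transcribed from a
#' published UK Biobank study of laboratory-free behavioral T2DM risk: the
#' final multivariate hazard table (printed beta, HR, HR%, CI, p per term),
#' the cohort-wise neural influence scores with sign-stability percentages
#' and their T2DM-minus-Healthy differences, and the per-variable network
#' centralities for both health states with their shifts.  They serve as
#' *inputs* to consistency checks — the package's own arithmetic (HR%
#' derivation, risk-score accumulation, difference matrices, centrality
#' deltas) is validated against the printed derived columns — not as
#' quantities the synthetic pipeline is expected to re-estimate.
#'
#' @return A data frame (see each table's columns).
#' @name reference_tables
NULL

ref_path <- function(file)
  system.file("extdata", file, package = "behavnet", mustWork = TRUE)

#' @rdname reference_tables
#' @export
reference_hazard_table <- function() {
  utils::read.csv(ref_path("ref_hazard_table.csv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_influence_scores <- function() {
  utils::read.csv(ref_path("ref_influence_scores.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_centrality_shifts <- function() {
  utils::read.csv(ref_path("ref_centrality_shifts.csv"),
                  stringsAsFactors = FALSE)
}

#' Published risk-stratification score ranges
#'
#' The five printed per-stratum linear-predictor ranges of the reference
#' study, used to validate stratum assignment of worked risk-score
#' examples.
#'
#' @return A [risk_stratification()] built from the printed ranges.
#' @export
reference_stratification <- function() {
  risk_stratification(ranges = list(
    very_low = c(-1.67, 0.22), low = c(0.23, 0.40),
    moderate = c(0.41, 0.70), high = c(0.71, 1.11),
    very_high = c(1.12, 2.75)))
}
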