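#' Published decile counts from a melanoma case-control series
#'
#' Case/control counts by decile of the standardized PRS (deciles of the
#' control distribution; deciles 5 and 6 merged as the reference group),
#' from a published single-centre series of 270 melanoma patients with a
#' suspected genetic predisposition and 296 healthy blood-donor
#' controls.  The crude decile odds ratios of that study are exactly
#' recomputable from these counts with [decile_or_table()] or
#' [or_2x2()].
#'
#' @return Data frame with columns `group`, `n_case`, `n_control`.
#' @export
melanoma_decile_counts <- function() {
  utils::read.table(system.file("extdata", "melanoma_decile_counts.tsv",
                                package = "melprs"),
                    header = TRUE, sep = "\t", colClasses =
                      c("character", "integer", "integer"))
}

#' Published decile counts for multiple vs single primary melanoma
#'
#' Counts of multiple-primary (MPM, treated as cases) and
#' single-primary (SPM) melanoma patients by decile of the case PRS
#' distribution (decile 1 is the reference), from the same published
#' series as [melanoma_decile_counts()].
#'
#' @return Data frame with columns `group`, `n_case` (MPM),
#'   `n_control` (SPM).
#' @export
mpm_decile_counts <- function() {
  utils::read.table(system.file("extdata", "mpm_decile_counts.tsv",
                                package = "melprs"),
                    header = TRUE, sep = "\t", colClasses =
                      c("character", "integer", "integer"))
}

#' Published risk-factor counts for multiple vs single primary melanoma
#'
#' MPM/SPM counts by level of each phenotypic risk factor (age at
#' diagnosis, sex, eye and hair color, phototype, sunburn frequency,
#' nevus count) from the same published series, with the reference level
#' of each univariate contrast flagged.
#'
#' @return Data frame with columns `variable`, `level`, `n_mpm`,
#'   `n_spm`, `is_ref`.
#' @export
mpm_risk_factor_counts <- function() {
  utils::read.table(system.file("extdata", "mpm_risk_factor_counts.tsv",
                                package = "melprs"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
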