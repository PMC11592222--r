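#' Run the full PRS case-control analysis pipeline
#'
#' Chains every stage on file inputs: read weights and genotypes, apply
#' panel QC (strand-ambiguous removal, depth filtering, LD pruning),
#' compute and control-standardize the score, stratify melanoma risk by
#' control-deciles with crude and age/sex-adjusted odds ratios, compare
#' the discrimination of the decile model with and without age and sex
#' (paired DeLong), summarize the score across case phenotype strata,
#' and - among cases - analyze multiple-primary-melanoma risk by case
#' deciles and per-SD.  All report tables are written as TSV into
#' `out_dir`, the QC trail as JSON.
#'
#' @param vcf_path Path to the genotype VCF.
#' @param weights_path Path to the weights TSV/CSV.
#' @param phenotype_path Path to the phenotype TSV (columns as written
#'   by [write_cohort()]).
#' @param out_dir Output directory for report files.
#' @param min_depth Per-genotype read-depth threshold. Default 30.
#' @param max_r2 LD pruning threshold. Default 0.45.
#' @param normalize_chr Passed to [read_genotypes_vcf()].
#' @return Invisibly, a list with all intermediate objects: `weights`,
#'   `qc`, `scores`, `melanoma_or`, `melanoma_or_adjusted`, `auc_prs`,
#'   `auc_full`, `delong`, `strata`, `mpm_or_decile`, `mpm_per_sd`.
#' @export
run_prs_pipeline <- function(vcf_path, weights_path, phenotype_path,
                             out_dir, min_depth = 30, max_r2 = 0.45,
                             normalize_chr = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  weights <- read_weights(weights_path)
  amb <- filter_ambiguous(weights)
  weights <- amb$weights
  geno <- read_genotypes_vcf(vcf_path, weights, min_depth = min_depth,
                             normalize_chr = normalize_chr)
  pruned <- ld_prune(geno$genotypes, weights, max_r2 = max_r2)
  keep <- pruned$retained
  weights <- validate_weights(weights[weights$snp_id %in% keep, ,
                                      drop = FALSE])
  dosages <- geno$genotypes[, keep, drop = FALSE]
  class(dosages) <- c("prs_genotypes", "matrix", "array")

  pheno <- read_phenotypes(phenotype_path)
  stopifnot(all(rownames(dosages) %in% pheno$individual_id))
  pheno <- pheno[match(rownames(dosages), pheno$individual_id), ]
  is_case <- pheno$status == "case"

  raw <- compute_prs(dosages, weights)
  scores <- standardize_scores(raw, control_mask = !is_case)
  write_scoreset(scores, file.path(out_dir, "scores.tsv"))

  qc <- qc_report(removed_ambiguous = amb$qc$removed_ambiguous,
                  removed_ld = pruned$qc$removed_ld,
                  genotypes_set_missing_low_depth =
                    geno$qc$genotypes_set_missing_low_depth,
                  snps_missing_from_vcf = geno$qc$snps_missing_from_vcf)
  write_qc_report(qc, file.path(out_dir, "qc_report.json"))

  # melanoma risk by control-deciles, merged 5-6 reference
  scheme <- decile_scheme(decile_cutpoints(scores$std[!is_case]),
                          merge = list("5-6" = c(5, 6)),
                          reference = "5-6")
  labels <- assign_deciles(scores$std, scheme)
  outcome <- as.numeric(is_case)
  mel_or <- decile_or_table(labels, outcome)
  sexm <- as.numeric(pheno$sex == "M")
  covars <- cbind(age = pheno$age_at_sampling, male = sexm)
  mel_or_adj <- decile_or_table(labels, outcome, covariates = covars)
  write_or_table(mel_or, file.path(out_dir, "melanoma_decile_or.tsv"))
  write_or_table(mel_or_adj,
                 file.path(out_dir, "melanoma_decile_or_adjusted.tsv"))

  # discrimination: decile-categorized PRS model vs + age and sex
  x_base <- stats::model.matrix(~labels)
  x_full <- cbind(x_base, covars)
  dl <- compare_nested_models(x_base, x_full, outcome)
  auc_prs <- roc_auc(attr(dl, "fit_base")$fitted, outcome)
  auc_full <- roc_auc(attr(dl, "fit_full")$fitted, outcome)
  utils::write.table(roc_points(attr(dl, "fit_full")$fitted, outcome),
                     file.path(out_dir, "roc_full_model.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # score by phenotype strata (cases only carry phenotypes)
  strata_cols <- c("eye_color", "hair_color", "phototype", "sunburns",
                   "nevi", "family_history")
  strata <- lapply(strata_cols, function(col)
    strata_summary(scores$std[is_case], pheno[[col]][is_case]))
  names(strata) <- strata_cols
  for (col in strata_cols)
    write_strata_summary(strata[[col]],
                         file.path(out_dir,
                                   paste0("strata_", col, ".tsv")))

  # MPM vs SPM among cases: case-decile ORs (reference decile 1) and
  # per-SD OR of the continuous score
  mpm <- as.numeric(pheno$n_melanomas[is_case] > 1)
  case_scores <- scores$std[is_case]
  mpm_or <- NULL; mpm_sd <- NULL
  if (sum(!is.na(mpm)) >= 20 && length(unique(stats::na.omit(mpm))) == 2) {
    ok <- !is.na(mpm)
    case_scheme <- decile_scheme(decile_cutpoints(case_scores[ok]),
                                 reference = "1")
    mpm_or <- decile_or_table(assign_deciles(case_scores[ok],
                                             case_scheme), mpm[ok])
    mpm_sd <- per_sd_or(case_scores[ok], mpm[ok])
    write_or_table(mpm_or, file.path(out_dir, "mpm_decile_or.tsv"))
    write_or_table(mpm_sd, file.path(out_dir, "mpm_per_sd_or.tsv"))
  }

  invisible(list(weights = weights, qc = qc, scores = scores,
                 melanoma_or = mel_or, melanoma_or_adjusted = mel_or_adj,
                 auc_prs = auc_prs, auc_full = auc_full, delong = dl,
                 strata = strata, mpm_or_decile = mpm_or,
                 mpm_per_sd = mpm_sd))
}
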