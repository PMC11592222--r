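#' Compute the weighted-allele polygenic risk score
#'
#' Per individual, the raw score is the weighted sum over panel SNPs of
#' the effect-allele dosage times the per-allele log odds ratio:
#' `sum_i beta_i * x_i` with `x_i` in \{0, 1, 2\}.
#'
#' @param genotypes A `prs_genotypes` dosage matrix; its SNPs must be a
#'   subset of the weights panel.
#' @param weights A `prs_weights` table.
#' @param missing_policy How to treat missing dosages:
#'   `"impute_mean_dosage"` (default) replaces a missing dosage with the
#'   mean non-missing dosage of that SNP across all individuals;
#'   `"error"` fails, naming the first offending individual and SNP.
#' @return Named numeric vector of raw scores, one per individual.
#' @export
compute_prs <- function(genotypes, weights,
                        missing_policy = c("impute_mean_dosage", "error")) {
  missing_policy <- match.arg(missing_policy)
  weights <- validate_weights(weights)
  snps <- colnames(genotypes)
  if (!all(snps %in% weights$snp_id))
    stop("genotype matrix contains SNPs absent from the weights table")
  beta <- weights$beta[match(snps, weights$snp_id)]
  x <- matrix(as.numeric(genotypes), nrow = nrow(genotypes),
              dimnames = dimnames(genotypes))
  if (anyNA(x)) {
    if (missing_policy == "error") {
      ij <- which(is.na(x), arr.ind = TRUE)[1L, ]
      stop("missing dosage for individual ", rownames(x)[ij[1L]],
           " at SNP ", colnames(x)[ij[2L]], " under missing_policy = 'error'")
    }
    mu <- colMeans(x, na.rm = TRUE)
    if (anyNA(mu) || any(is.nan(mu)))
      stop("SNP(s) with all dosages missing: ",
           paste(colnames(x)[is.nan(mu)], collapse = ", "))
    for (j in which(colSums(is.na(x)) > 0L))
      x[is.na(x[, j]), j] <- mu[j]
  }
  drop(x %*% beta)
}

#' Standardize scores against a control series
#'
#' Centers and scales every individual's raw score by the mean and the
#' sample (n-1 denominator) standard deviation computed on the controls
#' only, so that controls have standardized mean 0 and SD 1 and cases are
#' expressed in control-SD units.
#'
#' @param raw Named numeric vector of raw scores.
#' @param control_mask Logical vector, `TRUE` for controls.
#' @return A `prs_scoreset` list: `individual_ids`, `raw`, `std`, and
#'   `params` (list with the control `mean` and `sd` used).
#' @export
standardize_scores <- function(raw, control_mask) {
  stopifnot(is.numeric(raw), is.logical(control_mask),
            length(raw) == length(control_mask))
  ctrl <- raw[control_mask]
  if (length(ctrl) < 2L) stop("need at least 2 controls to standardize")
  m <- mean(ctrl)
  s <- stats::sd(ctrl)
  if (!is.finite(s) || s == 0)
    stop("control scores have zero standard deviation")
  structure(list(individual_ids = names(raw),
                 raw = raw,
                 std = (raw - m) / s,
                 params = list(mean = m, sd = s)),
            class = "prs_scoreset")
}

#' @export
print.prs_scoreset <- function(x, ...) {
  cat("PRS score set:", length(x$raw), "individuals\n")
  cat(sprintf("  control standardization: mean %.3f, SD %.3f\n",
              x$params$mean, x$params$sd))
  cat(sprintf("  standardized score range: [%.3f, %.3f]\n",
              min(x$std), max(x$std)))
  invisible(x)
}

#' Export a score set as TSV (scores) and JSON (parameters)
#'
#' @param scoreset A `prs_scoreset`.
#' @param path Output TSV path; the standardization parameters are
#'   written next to it with extension `.params.json`.
#' @return `path`, invisibly.
#' @export
write_scoreset <- function(scoreset, path) {
  stopifnot(inherits(scoreset, "prs_scoreset"))
  utils::write.table(
    data.frame(individual_id = scoreset$individual_ids,
               raw_score = scoreset$raw,
               std_score = scoreset$std),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(scoreset$params,
                       sub("(\\.tsv)?$", ".params.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
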