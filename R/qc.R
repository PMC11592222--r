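#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation between two dosage vectors, the composite
#' (genotype-level) linkage-disequilibrium measure used for panel pruning.
#' Pairs with a missing value in either vector are excluded.
#'
#' @param x,y Numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
genotype_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  if (length(x) < 2L) stop("fewer than 2 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in a dosage vector: r-squared undefined")
  stats::cor(x, y)^2
}

#' Greedy LD pruning of a SNP panel
#'
#' Walks the panel in (chrom, pos) order and, for every pair of retained
#' SNPs whose dosage r-squared exceeds `max_r2`, drops the SNP with the
#' smaller absolute effect size (ties: the later one in order), so the
#' more informative marker of each correlated pair survives.  On exit no
#' retained pair exceeds the threshold.
#'
#' Pairs where either SNP has zero dosage variance (monomorphic in the
#' data) cannot be scored for LD and are left untouched.
#'
#' @param genotypes A `prs_genotypes` dosage matrix aligned to `weights`.
#' @param weights A `prs_weights` table covering the matrix columns.
#' @param max_r2 Pruning threshold on pairwise r-squared. Default 0.45.
#' @return A list with `retained` (character snp_ids, original panel
#'   order) and `qc` (a `prs_qc_report` whose `removed_ld` records each
#'   kept/dropped pair with its r-squared).
#' @export
ld_prune <- function(genotypes, weights, max_r2 = 0.45) {
  weights <- validate_weights(weights)
  snps <- colnames(genotypes)
  if (!all(snps %in% weights$snp_id))
    stop("genotype matrix contains SNPs absent from the weights table")
  w <- weights[match(snps, weights$snp_id), , drop = FALSE]
  ord <- order(w$chrom, w$pos)

  alive <- rep(TRUE, length(snps))
  rec_kept <- character(); rec_drop <- character(); rec_r2 <- numeric()
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!alive[i]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (!alive[j]) next
      r2 <- tryCatch(genotype_r2(genotypes[, i], genotypes[, j]),
                     error = function(e) NA_real_)
      if (is.na(r2) || r2 <= max_r2) next
      drop <- if (abs(w$beta[i]) < abs(w$beta[j])) i else j
      keep <- if (drop == i) j else i
      alive[drop] <- FALSE
      rec_kept <- c(rec_kept, snps[keep])
      rec_drop <- c(rec_drop, snps[drop])
      rec_r2 <- c(rec_r2, r2)
      if (drop == i) break
    }
  }
  list(retained = snps[alive],
       qc = qc_report(removed_ld = data.frame(kept = rec_kept,
                                              dropped = rec_drop,
                                              r2 = rec_r2)))
}
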