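#' Read a per-SNP weights table
#'
#' Reads the effect-size panel that defines a polygenic risk score: one row
#' per SNP with its genomic location, effect (alternative) allele, other
#' allele, and per-allele log odds ratio.  The file may be tab- or
#' comma-delimited and must carry a header naming the six columns
#' `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`.
#'
#' @param path Path to a TSV/CSV weights file.
#' @return A `prs_weights` data frame with columns `snp_id` (character),
#'   `chrom` (character), `pos` (integer, 1-based), `effect_allele`,
#'   `other_allele` (single uppercase bases), and `beta` (numeric log OR),
#'   in file order.
#' @export
read_weights <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("weights file lacks column(s): ", paste(missing_cols, collapse = ", "))
  beta <- suppressWarnings(as.numeric(raw$beta))
  if (anyNA(beta) || any(!is.finite(beta)))
    stop("unparseable or non-finite beta at row(s): ",
         paste(which(is.na(beta) | !is.finite(beta)), collapse = ", "))
  pos <- suppressWarnings(as.integer(raw$pos))
  if (anyNA(pos)) stop("unparseable position in weights file")
  w <- data.frame(snp_id = raw$snp_id,
                  chrom = raw$chrom,
                  pos = pos,
                  effect_allele = toupper(raw$effect_allele),
                  other_allele = toupper(raw$other_allele),
                  beta = beta,
                  stringsAsFactors = FALSE)
  validate_weights(w)
}

#' Write a weights table
#'
#' Inverse of [read_weights()]; writes a tab-delimited file with the
#' canonical six-column header.
#'
#' @param weights A `prs_weights` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  weights <- validate_weights(weights)
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_weights <- function(w) {
  stopifnot(is.data.frame(w))
  if (nrow(w)) {
    if (anyDuplicated(w$snp_id))
      stop("duplicate snp_id in weights: ",
           paste(unique(w$snp_id[duplicated(w$snp_id)]), collapse = ", "))
    if (any(!nzchar(w$snp_id))) stop("empty snp_id in weights")
    key <- paste(w$chrom, w$pos)
    if (anyDuplicated(key))
      stop("duplicate (chrom, pos) in weights: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    ok <- w$effect_allele %in% c("A", "C", "G", "T") &
      w$other_allele %in% c("A", "C", "G", "T")
    if (any(!ok))
      stop("non-ACGT allele for SNP(s): ",
           paste(w$snp_id[!ok], collapse = ", "))
    if (any(w$effect_allele == w$other_allele))
      stop("effect allele equals other allele for SNP(s): ",
           paste(w$snp_id[w$effect_allele == w$other_allele], collapse = ", "))
  }
  class(w) <- c("prs_weights", "data.frame")
  w
}

#' Remove strand-ambiguous SNPs from a weights panel
#'
#' A SNP is strand-ambiguous (palindromic) when its allele pair is \{A,T\}
#' or \{C,G\}: the two alleles are reverse complements of each other, so
#' the strand of the reporting study cannot be resolved from the alleles
#' alone.  Such SNPs are removed as a standard first QC step before
#' scoring; all other SNPs are retained in order.
#'
#' @param weights A `prs_weights` table.
#' @return A list with `weights` (the filtered panel) and `qc` (a
#'   `prs_qc_report`, see [qc_report()]) whose `removed_ambiguous` lists
#'   the dropped snp_ids.
#' @export
filter_ambiguous <- function(weights) {
  weights <- validate_weights(weights)
  amb <- is_palindromic(weights$effect_allele, weights$other_allele)
  list(weights = validate_weights(weights[!amb, , drop = FALSE]),
       qc = qc_report(removed_ambiguous = weights$snp_id[amb]))
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[a1] == a2)
}

#' Construct a QC report
#'
#' Bookkeeping container accumulated by the QC steps: ambiguous SNPs
#' removed, LD-pruned pairs with their r-squared, genotypes set missing for
#' low read depth, and panel SNPs absent from the genotype file.
#'
#' @param removed_ambiguous Character vector of snp_ids.
#' @param removed_ld Data frame with columns `kept`, `dropped`, `r2`.
#' @param genotypes_set_missing_low_depth Integer count.
#' @param snps_missing_from_vcf Character vector of snp_ids.
#' @return A `prs_qc_report` list.
#' @export
qc_report <- function(removed_ambiguous = character(),
                      removed_ld = data.frame(kept = character(),
                                              dropped = character(),
                                              r2 = numeric()),
                      genotypes_set_missing_low_depth = 0L,
                      snps_missing_from_vcf = character()) {
  stopifnot(all(removed_ld$r2 >= 0 & removed_ld$r2 <= 1))
  structure(list(removed_ambiguous = as.character(removed_ambiguous),
                 removed_ld = removed_ld,
                 genotypes_set_missing_low_depth =
                   as.integer(genotypes_set_missing_low_depth),
                 snps_missing_from_vcf = as.character(snps_missing_from_vcf)),
            class = "prs_qc_report")
}

#' @export
print.prs_qc_report <- function(x, ...) {
  cat("SNP panel QC report\n")
  cat("  strand-ambiguous SNPs removed:", length(x$removed_ambiguous), "\n")
  cat("  SNPs dropped by LD pruning:   ", nrow(x$removed_ld), "\n")
  cat("  genotypes set missing (depth):", x$genotypes_set_missing_low_depth, "\n")
  cat("  panel SNPs absent from VCF:   ", length(x$snps_missing_from_vcf), "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param qc A `prs_qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "prs_qc_report"))
  jsonlite::write_json(unclass(qc), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
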