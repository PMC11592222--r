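#' Read effect-allele dosages for a weights panel from a VCF
#'
#' Extracts per-sample genotypes for every SNP in the weights panel and
#' converts them to effect-allele dosages in \{0, 1, 2\}.  The VCF REF/ALT
#' pair must equal the weight record's allele pair; when the effect allele
#' is the VCF REF, the ALT count is flipped (`2 - alt count`).  No
#' complement-strand rescue is attempted: a site whose REF/ALT matches the
#' weight alleles only on the opposite strand is an error, because silent
#' strand flips corrupt scores (strand-ambiguous SNPs should already have
#' been removed with [filter_ambiguous()]).
#'
#' A genotype is set missing when the GT call is missing or when a
#' per-sample read depth (FORMAT `DP`) is present and below `min_depth`.
#' Panel SNPs with no matching VCF record yield a fully missing dosage
#' column and are listed in the QC report.
#'
#' @param path Path to a VCF (v4.x) file with per-sample GT.
#' @param weights A `prs_weights` table; sites are matched on
#'   (chrom, pos).
#' @param min_depth Minimum per-sample read depth; genotypes with DP below
#'   this are set missing.  Ignored when the VCF carries no DP. Default 30.
#' @param normalize_chr If `TRUE`, a leading `"chr"` prefix is stripped
#'   from both the VCF and the weights chromosomes before matching;
#'   otherwise chromosome strings are compared verbatim.
#' @return A list with `genotypes` (a `prs_genotypes` object: integer
#'   matrix of dosages, individuals in rows, panel SNPs in columns, `NA`
#'   for missing) and `qc` (a `prs_qc_report`).
#' @export
read_genotypes_vcf <- function(path, weights, min_depth = 30,
                               normalize_chr = FALSE) {
  weights <- validate_weights(weights)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix   # character matrix, one row per record
  chrom <- as.character(fix[, "CHROM"])
  wchrom <- weights$chrom
  if (normalize_chr) {
    chrom <- sub("^chr", "", chrom)
    wchrom <- sub("^chr", "", wchrom)
  }
  vkey <- paste(chrom, fix[, "POS"])
  wkey <- paste(wchrom, weights$pos)
  if (anyDuplicated(vkey[vkey %in% wkey]))
    stop("VCF contains duplicate records for panel site(s)")
  idx <- match(wkey, vkey)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- NULL
  if ("DP" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID)
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  samples <- colnames(gt)
  if (is.null(samples) || !length(samples))
    stop("VCF carries no sample genotype columns")

  n <- length(samples)
  p <- nrow(weights)
  dos <- matrix(NA_integer_, nrow = n, ncol = p,
                dimnames = list(samples, weights$snp_id))
  n_low_depth <- 0L
  missing_sites <- character()

  for (j in seq_len(p)) {
    i <- idx[j]
    if (is.na(i)) {
      missing_sites <- c(missing_sites, weights$snp_id[j])
      next
    }
    ref <- toupper(fix[i, "REF"])
    alt <- toupper(fix[i, "ALT"])
    if (grepl(",", alt, fixed = TRUE))
      stop("multi-allelic site for SNP ", weights$snp_id[j],
           " (ALT = ", alt, ")")
    ea <- weights$effect_allele[j]
    oa <- weights$other_allele[j]
    flip <- FALSE
    if (ref == oa && alt == ea) {
      flip <- FALSE
    } else if (ref == ea && alt == oa) {
      flip <- TRUE
    } else {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      strand_note <-
        if ((ref == comp[[oa]] && alt == comp[[ea]]) ||
            (ref == comp[[ea]] && alt == comp[[oa]]))
          " (alleles match only on the opposite strand; no rescue attempted)"
        else ""
      stop("VCF alleles ", ref, "/", alt, " incompatible with weights ",
           ea, "/", oa, " for SNP ", weights$snp_id[j], strand_note)
    }
    alt_count <- gt_to_alt_count(gt[i, ])
    if (!is.null(dp)) {
      low <- !is.na(dp[i, ]) & dp[i, ] < min_depth & !is.na(alt_count)
      n_low_depth <- n_low_depth + sum(low)
      alt_count[low] <- NA_integer_
    }
    dos[, j] <- if (flip) 2L - alt_count else alt_count
  }

  list(genotypes = new_genotypes(dos),
       qc = qc_report(genotypes_set_missing_low_depth = n_low_depth,
                      snps_missing_from_vcf = missing_sites))
}

# "0/1", "0|1", "1/1", "./." -> count of ALT alleles (NA on any missing)
gt_to_alt_count <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt)
  parts <- strsplit(gt[ok], "[/|]")
  cnt <- vapply(parts, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    v <- suppressWarnings(as.integer(a))
    if (anyNA(v) || any(v > 1L)) return(NA_integer_)
    sum(v)
  }, integer(1))
  out[ok] <- cnt
  out
}

#' Construct a dosage matrix object
#'
#' @param dosages Integer matrix, individuals x SNPs, values in
#'   \{0, 1, 2, NA\}; dimnames give individual and SNP ids.
#' @return A `prs_genotypes` matrix.
#' @export
new_genotypes <- function(dosages) {
  stopifnot(is.matrix(dosages))
  storage.mode(dosages) <- "integer"
  if ((is.null(rownames(dosages)) && nrow(dosages) > 0L) ||
      (is.null(colnames(dosages)) && ncol(dosages) > 0L))
    stop("dosage matrix requires individual and SNP dimnames")
  if (anyDuplicated(rownames(dosages))) stop("duplicate individual ids")
  if (anyDuplicated(colnames(dosages))) stop("duplicate SNP ids")
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  structure(dosages, class = c("prs_genotypes", "matrix", "array"))
}

#' @export
print.prs_genotypes <- function(x, ...) {
  cat("Effect-allele dosage matrix:", nrow(x), "individuals x",
      ncol(x), "SNPs;", sum(is.na(x)), "missing\n")
  invisible(x)
}
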