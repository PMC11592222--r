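# Small in-code fixtures shared across test files.

make_weights <- function(snp_id = c("rs1", "rs2", "rs3"),
                         chrom = c("1", "1", "2"),
                         pos = c(100L, 200L, 100L),
                         effect = c("A", "G", "C"),
                         other = c("G", "A", "T"),
                         beta = c(0.1, -0.2, 0.3)) {
  validate_weights(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                              effect_allele = effect, other_allele = other,
                              beta = beta, stringsAsFactors = FALSE))
}

make_dosages <- function(mat, individuals = NULL, snps = NULL) {
  if (is.null(individuals)) individuals <- sprintf("i%d", seq_len(nrow(mat)))
  if (is.null(snps)) snps <- sprintf("rs%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(individuals, snps)
  new_genotypes(mat)
}

# hand-written VCF for orientation / depth / error cases
write_test_vcf <- function(path, rows, samples = c("s1", "s2")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

vcf_row <- function(chrom, pos, id, ref, alt, cells, format = "GT:DP") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", format, cells),
        collapse = "\t")
}
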