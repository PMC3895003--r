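# Shared fixture builders: everything generated in code, no stored data.

# tiny deterministic allele matrix from explicit symbol rows
fixture_matrix <- function(symbols, labels) {
  M <- ncol(symbols) / 2L
  snps <- snp_defs(sprintf("rs%d", seq_len(M)), "1", seq_len(M) * 10L,
                   rep("T", M), rep("A", M))
  allele_matrix(symbols, snps, sprintf("s%02d", seq_len(nrow(symbols))),
                labels)
}

# moderate synthetic dataset with planted signal, shared by several files
signal_sim <- function(n_cases = 150, n_controls = 130, M = 200,
                       n_risk = 25, omega = 6, seed = 42) {
  generate_genotypes(synthetic_spec(
    n_cases = n_cases, n_controls = n_controls, M = M,
    risk_loci = risk_on_odd_compartments(n_risk, omega),
    missing_rate = 0, seed = seed))
}

# null dataset: labels carry no information
null_sim <- function(n_cases = 80, n_controls = 80, M = 150, seed = 11) {
  generate_genotypes(synthetic_spec(
    n_cases = n_cases, n_controls = n_controls, M = M,
    missing_rate = 0, seed = seed))
}

# hand-written 3-sample 2-SNP VCF, returned as a temp file path
write_fixture_vcf <- function(dir = tempdir()) {
  path <- file.path(dir, "fixture.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sampA", "sampB", "sampC", sep = "\t"),
    paste("1", "100", "rs1", "A", "T", ".", "PASS", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "200", "rs2", "C", "G", ".", "PASS", ".", "GT",
          "0/0", "0|1", "1/1", sep = "\t")), path)
  path
}

write_fixture_pheno <- function(ids, labels, dir = tempdir()) {
  path <- file.path(dir, paste0("pheno-", paste(ids, collapse = ""),
                                ".tsv"))
  writeLines(paste(ids, labels, sep = "\t"), path)
  path
}
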