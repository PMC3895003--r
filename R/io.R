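# File readers/writers for the formats the pipeline accepts: VCF (via vcfR),
# PLINK .ped/.map, the internal standard-form TSV, and the phenotype sidecar.

#' Read a phenotype sidecar TSV
#'
#' Two tab-separated columns, no header requirement enforced beyond names:
#' `sample_id` and `label` (values `disease` or `control`). A header line
#' `sample_id<TAB>label` is accepted and skipped.
#'
#' @param path file path.
#' @return Named character vector mapping sample id to label.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample_id", "label"))
  if (nrow(ph) && ph$sample_id[1] == "sample_id") ph <- ph[-1, , drop = FALSE]
  bad <- !(ph$label %in% c("disease", "control"))
  if (any(bad))
    stop("phenotype labels must be 'disease' or 'control'; offending: ",
         paste(unique(ph$label[bad]), collapse = ", "))
  stats::setNames(ph$label, ph$sample_id)
}

match_labels <- function(sample_ids, pheno) {
  unknown <- setdiff(sample_ids, names(pheno))
  if (length(unknown))
    stop("samples absent from phenotype file: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) " ..." else "")
  unname(pheno[sample_ids])
}

#' Read genotypes from VCF, PLINK ped/map, or standard-form TSV
#'
#' For `vcf` and `ped_map` the file is decoded to unordered nucleotide
#' genotype pairs plus SNP definitions, ready for [encode_standard_form()];
#' multi-allelic or non-SNP records are skipped with a warning. For `tsv`
#' the file is already in the standard organization and an
#' [allele_matrix()] is returned directly.
#'
#' @param path genotype file. For `ped_map` give the `.ped` path; the
#'   matching `.map` is found by extension substitution (or pass `map`).
#' @param format one of `"vcf"`, `"ped_map"`, `"tsv"`.
#' @param pheno path to the phenotype sidecar TSV (see [read_phenotypes()]).
#' @param map optional explicit `.map` path for `ped_map`.
#' @return For `vcf`/`ped_map`: a list with `genotypes` (character matrix of
#'   two-letter pairs, `NA` missing), `snps`, `sample_ids`, `labels`.
#'   For `tsv`: an [allele_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "ped_map", "tsv"),
                           pheno, map = NULL) {
  format <- match.arg(format)
  switch(format,
         vcf = read_vcf_genotypes(path, pheno),
         ped_map = read_ped_map(path, map, pheno),
         tsv = read_standard_tsv(path, pheno))
}

read_vcf_genotypes <- function(path, pheno) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  snp_ok <- nchar(fx$REF) == 1L & nchar(fx$ALT) == 1L &
    !grepl(",", fx$ALT, fixed = TRUE) &
    fx$REF %in% c("A", "C", "G", "T") & fx$ALT %in% c("A", "C", "G", "T")
  if (any(!snp_ok))
    warning(sum(!snp_ok), " non-biallelic-SNP record(s) skipped: ",
            paste(utils::head(fx$ID[!snp_ok], 5), collapse = ", "))
  fx <- fx[snp_ok, , drop = FALSE]
  gt <- gt[snp_ok, , drop = FALSE]
  sample_ids <- colnames(gt)
  M <- nrow(fx)
  geno <- matrix(NA_character_, length(sample_ids), M)
  for (k in seq_len(M)) {
    alleles <- c(fx$REF[k], fx$ALT[k])
    g <- gt[k, ]
    g <- sub("|", "/", g, fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)
    geno[, k] <- vapply(parts, function(p) {
      if (length(p) != 2L || any(p == ".") || anyNA(p)) return(NA_character_)
      i <- suppressWarnings(as.integer(p))
      if (anyNA(i) || any(i < 0L) || any(i > 1L))
        stop("malformed GT field '", paste(p, collapse = "/"), "'")
      paste0(alleles[i[1] + 1L], alleles[i[2] + 1L])
    }, character(1))
  }
  ids <- fx$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fx$CHROM[noid], ":", fx$POS[noid])
  snps <- snp_defs(ids, fx$CHROM, as.integer(fx$POS), fx$REF, fx$ALT)
  labels <- match_labels(sample_ids, read_phenotypes(pheno))
  list(genotypes = geno, snps = snps, sample_ids = sample_ids,
       labels = labels)
}

read_ped_map <- function(ped_path, map_path = NULL, pheno) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path)
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("malformed .map: expected >= 4 columns")
  names(map)[1:4] <- c("chromosome", "snp_id", "cm", "position")
  ped <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  M <- nrow(map)
  if (ncol(ped) != 6L + 2L * M)
    stop("malformed .ped: ", ncol(ped), " columns for ", M, " map SNPs")
  sample_ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(M) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(M), drop = FALSE])
  miss <- a1 == "0" | a2 == "0"
  geno <- matrix(paste0(a1, a2), nrow(ped), M)
  geno[miss] <- NA_character_
  # allele pair per SNP from the observed letters
  alleles <- lapply(seq_len(M), function(k) {
    obs <- sort(unique(c(a1[!miss[, k], k], a2[!miss[, k], k])))
    if (length(obs) > 2L)
      stop("SNP ", map$snp_id[k], " has >2 alleles: ",
           paste(obs, collapse = ","))
    if (length(obs) == 1L) obs <- c(obs, obs)  # monomorphic in file
    obs
  })
  mono <- vapply(alleles, function(a) a[1] == a[2], logical(1))
  if (any(mono))
    warning(sum(mono), " monomorphic SNP(s) in .ped skipped: ",
            paste(utils::head(map$snp_id[mono], 5), collapse = ", "))
  keep <- !mono
  snps <- snp_defs(map$snp_id[keep], map$chromosome[keep],
                   as.integer(map$position[keep]),
                   vapply(alleles[keep], `[`, character(1), 1L),
                   vapply(alleles[keep], `[`, character(1), 2L))
  labels <- match_labels(sample_ids, read_phenotypes(pheno))
  list(genotypes = geno[, keep, drop = FALSE], snps = snps,
       sample_ids = sample_ids, labels = labels)
}

#' Read / write the internal standard-form TSV
#'
#' Header row of locus ids `rsID.o` / `rsID.e` (odd/even compartments in
#' order), then one row per sample: sample id followed by cells in
#' \{1, 2, NA\}. SNP metadata beyond the id is not stored in this format;
#' placeholder chromosome/position and alleles are used on read.
#'
#' @param path file path.
#' @param pheno phenotype sidecar TSV path, or a named label vector.
#' @return An [allele_matrix()].
#' @export
read_standard_tsv <- function(path, pheno) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, row.names = 1L,
                           stringsAsFactors = FALSE)
  ids <- colnames(tab)
  if (length(ids) %% 2L != 0L)
    stop("standard-form TSV must have an even number of locus columns")
  odd <- ids[seq(1L, length(ids), by = 2L)]
  even <- ids[seq(2L, length(ids), by = 2L)]
  if (!all(grepl("\\.o$", odd)) || !all(grepl("\\.e$", even)) ||
      !identical(sub("\\.o$", "", odd), sub("\\.e$", "", even)))
    stop("locus columns must alternate rsID.o, rsID.e per SNP")
  snp_ids <- sub("\\.o$", "", odd)
  # alleles unknown in this format; use placeholders with valid ordering
  snps <- snp_defs(snp_ids, chromosome = "NA",
                   position = seq_along(snp_ids),
                   allele1 = "T", allele2 = "A")
  ph <- if (is.character(pheno) && length(pheno) == 1L && file.exists(pheno))
    read_phenotypes(pheno) else pheno
  labels <- match_labels(rownames(tab), ph)
  allele_matrix(as.matrix(tab), snps, rownames(tab), labels)
}

#' @rdname read_standard_tsv
#' @param m an [allele_matrix()].
#' @export
write_standard_tsv <- function(m, path) {
  tab <- as.data.frame(m$symbols, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write the phenotype sidecar TSV
#' @param m an [allele_matrix()].
#' @param path file path.
#' @export
write_phenotype_tsv <- function(m, path) {
  utils::write.table(
    data.frame(sample_id = m$sample_ids, label = as.character(m$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
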