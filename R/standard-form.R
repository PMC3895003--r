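#' Fixed nucleotide alias order
#'
#' Nucleotides are aliased by consecutive integers in the fixed order
#' A < C < G < T. Only the within-SNP ranking of the two alleles matters for
#' the standard organization, so any fixed total order is equivalent; this
#' one is frozen and exported so file readers and tests agree on it.
#'
#' @format Named integer vector of length 4.
#' @export
NUCLEOTIDE_ALIAS <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Build a SNP definition table
#'
#' A SNP definition records the identity, position and the two alleles of a
#' biallelic SNP. The allele with the larger alias under [NUCLEOTIDE_ALIAS]
#' is stored as `allele_hi` (re-aliased to symbol 2 in the standard
#' organization), the other as `allele_lo` (symbol 1).
#'
#' @param snp_id character vector of ref-SNP identifiers.
#' @param chromosome chromosome labels.
#' @param position integer coordinates (1-based).
#' @param allele1,allele2 the two alleles of each SNP, in any order, each in
#'   `A`, `C`, `G`, `T`.
#' @return A `data.frame` with columns `snp_id`, `chromosome`, `position`,
#'   `allele_hi`, `allele_lo`.
#' @examples
#' snp_defs("rs1", "1", 100, "A", "T")  # allele_hi is "T"
#' @export
snp_defs <- function(snp_id, chromosome, position, allele1, allele2) {
  allele1 <- toupper(allele1); allele2 <- toupper(allele2)
  bad <- !(allele1 %in% names(NUCLEOTIDE_ALIAS)) |
         !(allele2 %in% names(NUCLEOTIDE_ALIAS))
  if (any(bad))
    stop("non-nucleotide allele for SNP(s): ",
         paste(snp_id[bad], collapse = ", "))
  if (any(allele1 == allele2))
    stop("monomorphic SNP definition (identical alleles): ",
         paste(snp_id[allele1 == allele2], collapse = ", "))
  a1 <- NUCLEOTIDE_ALIAS[allele1]; a2 <- NUCLEOTIDE_ALIAS[allele2]
  hi <- ifelse(a1 > a2, allele1, allele2)
  lo <- ifelse(a1 > a2, allele2, allele1)
  data.frame(snp_id = as.character(snp_id),
             chromosome = as.character(chromosome),
             position = as.integer(position),
             allele_hi = hi, allele_lo = lo,
             stringsAsFactors = FALSE, row.names = NULL)
}

locus_ids <- function(snps) {
  as.vector(rbind(paste0(snps$snp_id, ".o"), paste0(snps$snp_id, ".e")))
}

#' Construct an allele matrix in the standard organization
#'
#' The container used throughout the package: a samples x (2M) integer
#' matrix of symbols in \{1, 2\} (NA marks missing), where columns 2k-1 and
#' 2k are the odd and even allele compartments of SNP k, plus locus
#' metadata, sample identifiers and case/control labels.
#'
#' @param symbols integer matrix, samples x 2M, entries in `c(1L, 2L, NA)`.
#' @param snps SNP definition table from [snp_defs()], one row per SNP.
#' @param sample_ids character vector, one per row of `symbols`.
#' @param labels factor or character, per-sample cohort, levels
#'   `disease`/`control`.
#' @return An object of class `allele_matrix`: a list with elements
#'   `symbols`, `loci` (per-column metadata with `snp_index`, `compartment`,
#'   SNP fields), `sample_ids`, `labels`.
#' @export
allele_matrix <- function(symbols, snps, sample_ids, labels) {
  symbols <- as.matrix(symbols)
  storage.mode(symbols) <- "integer"
  M <- nrow(snps)
  if (ncol(symbols) != 2L * M)
    stop("symbols must have 2 columns per SNP (got ", ncol(symbols),
         " columns for ", M, " SNPs)")
  if (nrow(symbols) != length(sample_ids))
    stop("sample_ids length does not match rows of symbols")
  labels <- factor(as.character(labels), levels = c("disease", "control"))
  if (anyNA(labels))
    stop("labels must be 'disease' or 'control'")
  ok <- symbols %in% c(1L, 2L, NA_integer_)
  if (!all(ok)) stop("symbols must be 1, 2 or NA")
  loci <- data.frame(
    locus_id = locus_ids(snps),
    snp_index = rep(seq_len(M), each = 2L),
    compartment = rep(c("odd", "even"), M),
    snps[rep(seq_len(M), each = 2L), , drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL)
  colnames(symbols) <- loci$locus_id
  rownames(symbols) <- sample_ids
  structure(list(symbols = symbols, loci = loci,
                 sample_ids = as.character(sample_ids), labels = labels),
            class = "allele_matrix")
}

#' @export
print.allele_matrix <- function(x, ...) {
  n <- length(x$sample_ids)
  M <- nrow(x$loci) / 2L
  nmiss <- sum(is.na(x$symbols))
  cat("allele_matrix:", n, "samples x", nrow(x$loci),
      "allele loci (", M, "SNPs )\n")
  cat("  cohorts:", sum(x$labels == "disease"), "disease /",
      sum(x$labels == "control"), "control\n")
  cat("  missing entries:", nmiss,
      sprintf("(%.4g%%)\n", 100 * nmiss / length(x$symbols)))
  invisible(x)
}

#' @export
dim.allele_matrix <- function(x) dim(x$symbols)

cohort_rows <- function(m, cohort = c("disease", "control")) {
  cohort <- match.arg(cohort)
  which(m$labels == cohort)
}

#' Encode genotypes into the standard organization
#'
#' Re-encodes unordered diploid genotypes as ordered (odd, even) allele
#' compartments aliased 2/1: the allele with the larger nucleotide alias is
#' written first, so a heterozygote always encodes (2, 1), a homozygote for
#' the high allele (2, 2), and a homozygote for the low allele (1, 1).
#' A missing genotype encodes (NA, NA).
#'
#' @param genotypes character matrix, samples x M, each entry the two
#'   acquired alleles as a two-letter string (e.g. `"AT"`, `"CC"`), or `NA`
#'   (also accepted: `""`, `"00"`, `"NN"`) for missing.
#' @param snps SNP definition table from [snp_defs()], one row per column of
#'   `genotypes`.
#' @param sample_ids,labels passed to [allele_matrix()].
#' @return An [allele_matrix()].
#' @examples
#' snps <- snp_defs(c("rs1","rs2","rs3"), "1", c(10,20,30),
#'                  c("A","C","C"), c("T","G","T"))
#' g <- rbind(c("AT", "CC", "TT"))
#' m <- encode_standard_form(g, snps, "s1", "disease")
#' m$symbols  # (2,1) (1,1) (2,2)
#' @export
encode_standard_form <- function(genotypes, snps, sample_ids, labels) {
  genotypes <- as.matrix(genotypes)
  M <- nrow(snps)
  if (ncol(genotypes) != M)
    stop("genotypes has ", ncol(genotypes), " columns but ", M,
         " SNPs are defined")
  n <- nrow(genotypes)
  symbols <- matrix(NA_integer_, n, 2L * M)
  miss_tokens <- c(NA, "", "00", "0", "NN", "..", "--")
  for (k in seq_len(M)) {
    g <- toupper(genotypes[, k])
    g[g %in% miss_tokens] <- NA
    obs <- !is.na(g)
    a1 <- substr(g[obs], 1L, 1L)
    a2 <- substr(g[obs], 2L, 2L)
    hi <- snps$allele_hi[k]; lo <- snps$allele_lo[k]
    valid <- a1 %in% c(hi, lo) & a2 %in% c(hi, lo) & nchar(g[obs]) == 2L
    if (!all(valid))
      stop("genotype with allele outside {", hi, ",", lo, "} at SNP ",
           snps$snp_id[k], ": ",
           paste(unique(g[obs][!valid]), collapse = ", "))
    n_hi <- (a1 == hi) + (a2 == hi)
    odd <- ifelse(n_hi >= 1L, 2L, 1L)
    even <- ifelse(n_hi == 2L, 2L, 1L)
    symbols[obs, 2L * k - 1L] <- odd
    symbols[obs, 2L * k] <- even
  }
  allele_matrix(symbols, snps, sample_ids, labels)
}

#' Decode an allele matrix back to nucleotide genotypes
#'
#' Inverse of [encode_standard_form()] up to within-pair order: symbols are
#' mapped back to nucleotides through the SNP definitions, yielding
#' genotypes in standard order (high allele first).
#'
#' @param m an [allele_matrix()].
#' @return Character matrix samples x M of two-letter genotype strings
#'   (`NA` where either compartment is missing).
#' @export
decode_standard_form <- function(m) {
  M <- nrow(m$loci) / 2L
  out <- matrix(NA_character_, nrow(m$symbols), M)
  for (k in seq_len(M)) {
    so <- m$symbols[, 2L * k - 1L]
    se <- m$symbols[, 2L * k]
    hi <- m$loci$allele_hi[2L * k - 1L]
    lo <- m$loci$allele_lo[2L * k - 1L]
    obs <- !is.na(so) & !is.na(se)
    out[obs, k] <- paste0(ifelse(so[obs] == 2L, hi, lo),
                          ifelse(se[obs] == 2L, hi, lo))
  }
  colnames(out) <- m$loci$snp_id[seq(1L, 2L * M, by = 2L)]
  rownames(out) <- m$sample_ids
  out
}

#' Drop SNPs with too many missing symbols
#'
#' Removes every SNP whose two allele columns jointly contain more than
#' `max_missing` missing entries over all samples (both compartments of a
#' SNP are always removed together). The removal report is attached as
#' attribute `"removal_report"` and is also available via
#' [removal_report()].
#'
#' @param m an [allele_matrix()].
#' @param max_missing integer; SNPs with strictly more missing symbols than
#'   this are dropped. Default 2.
#' @return The filtered [allele_matrix()].
#' @export
filter_missing_loci <- function(m, max_missing = 2L) {
  M <- nrow(m$loci) / 2L
  na_col <- colSums(is.na(m$symbols))
  na_snp <- na_col[seq(1L, 2L * M, by = 2L)] + na_col[seq(2L, 2L * M, by = 2L)]
  drop <- which(na_snp > max_missing)
  report <- data.frame(
    snp_id = m$loci$snp_id[2L * drop - 1L],
    n_missing = as.integer(na_snp[drop]),
    stringsAsFactors = FALSE, row.names = NULL)
  keep_cols <- rep(!(seq_len(M) %in% drop), each = 2L)
  snps_keep <- m$loci[m$loci$compartment == "odd" &
                        !(m$loci$snp_index %in% drop),
                      c("snp_id", "chromosome", "position",
                        "allele_hi", "allele_lo")]
  out <- allele_matrix(m$symbols[, keep_cols, drop = FALSE], snps_keep,
                       m$sample_ids, m$labels)
  attr(out, "removal_report") <- report
  out
}

#' Removal report of the last missingness filter
#' @param m an [allele_matrix()] returned by [filter_missing_loci()].
#' @return `data.frame` with `snp_id` and `n_missing`, or `NULL`.
#' @export
removal_report <- function(m) attr(m, "removal_report")

#' Impute remaining missing symbols by the column mode
#'
#' Each missing entry is replaced by the most frequent symbol of its allele
#' column, computed over all samples with both cohorts pooled (so no label
#' information leaks into the genotypes). An exact 50/50 tie imputes `tie`
#' (default symbol 2).
#'
#' @param m an [allele_matrix()].
#' @param tie symbol to impute on an exact tie; default `2L`.
#' @return An [allele_matrix()] with no missing entries.
#' @export
impute_modal <- function(m, tie = 2L) {
  stopifnot(tie %in% c(1L, 2L))
  sym <- m$symbols
  nacols <- which(colSums(is.na(sym)) > 0L)
  for (j in nacols) {
    col <- sym[, j]
    n2 <- sum(col == 2L, na.rm = TRUE)
    n1 <- sum(col == 1L, na.rm = TRUE)
    if (n1 + n2 == 0L)
      stop("column ", m$loci$locus_id[j], " is entirely missing; ",
           "cannot impute a mode")
    mode_sym <- if (n2 > n1) 2L else if (n1 > n2) 1L else tie
    sym[is.na(col), j] <- mode_sym
  }
  m$symbols <- sym
  m
}
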