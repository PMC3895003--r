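# Per-locus statistics: compartment probabilities, SNP pair probabilities,
# information content, allele (omega) and SNP (Omega) odds ratios, and the
# odds-ratio histograms / threshold-set-size curve.

#' Frequency of symbol 2 at each allele compartment
#'
#' @param m a cleaned [allele_matrix()] (no missing entries).
#' @param cohort `"disease"` or `"control"`.
#' @return Named numeric vector, one probability per allele column.
#' @export
compartment_probabilities <- function(m, cohort = c("disease", "control")) {
  rows <- cohort_rows(m, cohort)
  if (!length(rows)) stop("empty cohort: ", cohort)
  colMeans(m$symbols[rows, , drop = FALSE] == 2L)
}

#' SNP genotype pair probabilities
#'
#' Classifies each SNP genotype by the number of symbol-2 alleles it carries
#' (22, 21 or 11) and returns the observed pair frequencies, or the
#' independence products of the compartment probabilities.
#'
#' @param m a cleaned [allele_matrix()].
#' @param cohort `"disease"` or `"control"`.
#' @param mode `"observed"` (count genotype pairs) or `"independence"`
#'   (p22 = p_o * p_e etc., for analytic fixtures).
#' @param q_mode how the SNP-level symbol-2 probability `q` is defined:
#'   `"homozygous"` (q = p22, the default; see Details), `"carrier"`
#'   (q = p22 + p21) or `"allele_freq"` (q = (p_o + p_e) / 2).
#' @details The default `q_mode = "homozygous"` is the definition under
#'   which the SNP odds ratio of a risk SNP with one near-unity compartment
#'   stays near 1 while the allele odds ratio at that compartment is large:
#'   when p at one compartment approaches 1, q = p22 tracks the other
#'   compartment's probability, so Omega collapses to the uninformative
#'   compartment's ratio. The carrier definition instead compounds the two
#'   compartment ratios and loses that contrast.
#' @return `data.frame` with one row per SNP: `snp_id`, `p22`, `p21`, `p11`,
#'   `q`.
#' @export
snp_pair_probabilities <- function(m, cohort = c("disease", "control"),
                                   mode = c("observed", "independence"),
                                   q_mode = c("homozygous", "carrier",
                                              "allele_freq")) {
  mode <- match.arg(mode)
  q_mode <- match.arg(q_mode)
  rows <- cohort_rows(m, cohort)
  if (!length(rows)) stop("empty cohort: ", cohort)
  M <- nrow(m$loci) / 2L
  oidx <- seq(1L, 2L * M, by = 2L)
  so <- m$symbols[rows, oidx, drop = FALSE] == 2L
  se <- m$symbols[rows, oidx + 1L, drop = FALSE] == 2L
  if (mode == "observed") {
    n2 <- so + se  # 2, 1 or 0 copies of symbol 2
    p22 <- colMeans(n2 == 2L)
    p21 <- colMeans(n2 == 1L)
    p11 <- colMeans(n2 == 0L)
  } else {
    po <- colMeans(so); pe <- colMeans(se)
    p22 <- po * pe
    p21 <- po * (1 - pe) + (1 - po) * pe
    p11 <- (1 - po) * (1 - pe)
  }
  q <- switch(q_mode,
              homozygous = p22,
              carrier = p22 + p21,
              allele_freq = (colMeans(so) + colMeans(se)) / 2)
  data.frame(snp_id = m$loci$snp_id[oidx], p22 = p22, p21 = p21, p11 = p11,
             q = q, stringsAsFactors = FALSE, row.names = NULL)
}

odds <- function(p) p / (1 - p)

haldane_odds <- function(x, n) (x + 0.5) / (n - x + 0.5)

#' Allele odds ratio between disease and control
#'
#' omega = \[p_d/(1-p_d)\] / \[p_c/(1-p_c)\], the disease-vs-control odds
#' ratio of the symbol-2 frequency at one allele compartment. When a
#' probability sits at 0 or 1 and cohort sizes are supplied, the
#' Haldane-Anscombe continuity correction (0.5 added to each of the four
#' implied counts) replaces the infinite ratio; without cohort sizes the
#' boundary value is returned as `Inf`/`0` with a warning.
#'
#' @param p_d,p_c symbol-2 probabilities in the disease and control cohorts
#'   (vectorized).
#' @param n_d,n_c optional cohort sizes enabling the continuity correction.
#' @return Numeric vector of odds ratios. Attribute `"corrected"` flags the
#'   loci where the correction was applied.
#' @examples
#' allele_odds_ratio(0.9934, 0.9754)  # ~ 3.80
#' @export
allele_odds_ratio <- function(p_d, p_c, n_d = NULL, n_c = NULL) {
  if (any(p_d < 0 | p_d > 1 | p_c < 0 | p_c > 1))
    stop("probabilities must lie in [0, 1]")
  w <- odds(p_d) / odds(p_c)
  boundary <- p_d %in% c(0, 1) | p_c %in% c(0, 1)
  corrected <- rep(FALSE, length(w))
  if (any(boundary)) {
    if (is.null(n_d) || is.null(n_c)) {
      warning("boundary probability without cohort sizes; ",
              "returning uncorrected ratio")
    } else {
      x_d <- round(p_d * n_d); x_c <- round(p_c * n_c)
      w[boundary] <- (haldane_odds(x_d, n_d) / haldane_odds(x_c, n_c))[boundary]
      corrected <- boundary
    }
  }
  attr(w, "corrected") <- corrected
  w
}

#' SNP odds ratio between disease and control
#'
#' Same odds-ratio form applied to the SNP-level symbol-2 probability `q`
#' (by default q = p22 from observed pair counts; see
#' [snp_pair_probabilities()] for the alternatives).
#'
#' @param q_d,q_c SNP-level probabilities per cohort.
#' @inheritParams allele_odds_ratio
#' @return Numeric vector of SNP odds ratios.
#' @export
snp_odds_ratio <- function(q_d, q_c, n_d = NULL, n_c = NULL) {
  allele_odds_ratio(q_d, q_c, n_d, n_c)
}

binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

#' Information content of a SNP and its two allele compartments
#'
#' Compartment entropies H(p) = -p log2 p - (1-p) log2(1-p) and the SNP
#' entropy over the three genotype categories \{22, 21, 11\}
#' (0 log 0 = 0 throughout). The two-compartment representation always
#' carries at least as much information as the SNP genotype
#' (H_o + H_e >= H_snp).
#'
#' @param p_o,p_e symbol-2 probabilities at the odd and even compartments.
#' @param pair optional list/data.frame with `p22`, `p21`, `p11`; when
#'   omitted, the independence products of `p_o`, `p_e` are used.
#' @return List with `H_o`, `H_e`, `H_snp` (bits), vectorized.
#' @export
information_content <- function(p_o, p_e, pair = NULL) {
  if (is.null(pair)) {
    pair <- list(p22 = p_o * p_e,
                 p21 = p_o * (1 - p_e) + (1 - p_o) * p_e,
                 p11 = (1 - p_o) * (1 - p_e))
  }
  plogp <- function(p) ifelse(p > 0, -p * log2(p), 0)
  list(H_o = binary_entropy(p_o), H_e = binary_entropy(p_e),
       H_snp = plogp(pair$p22) + plogp(pair$p21) + plogp(pair$p11))
}

#' Full per-locus statistics table
#'
#' Computes, for every allele compartment and every SNP, the cohort
#' probabilities, entropies and odds ratios in one pass.
#'
#' @param m a cleaned [allele_matrix()] with both cohorts present.
#' @param pair_mode,q_mode passed to [snp_pair_probabilities()].
#' @return An object of class `locus_stats`: list with
#'   \describe{
#'     \item{allele}{per-compartment `data.frame`: `locus_id`, `snp_index`,
#'       `compartment`, `p_d`, `p_c`, `H_d`, `H_c`, `omega`, `corrected`.}
#'     \item{snp}{per-SNP `data.frame`: pair probabilities and `q` per
#'       cohort, `Omega`, SNP entropies.}
#'     \item{n_d, n_c}{cohort sizes.}
#'   }
#' @export
locus_stats <- function(m, pair_mode = c("observed", "independence"),
                        q_mode = c("homozygous", "carrier",
                                   "allele_freq")) {
  pair_mode <- match.arg(pair_mode)
  q_mode <- match.arg(q_mode)
  if (anyNA(m$symbols))
    stop("matrix contains missing symbols; filter and impute first")
  n_d <- sum(m$labels == "disease"); n_c <- sum(m$labels == "control")
  p_d <- compartment_probabilities(m, "disease")
  p_c <- compartment_probabilities(m, "control")
  omega <- allele_odds_ratio(p_d, p_c, n_d, n_c)
  allele <- data.frame(
    locus_id = m$loci$locus_id, snp_index = m$loci$snp_index,
    compartment = m$loci$compartment,
    p_d = unname(p_d), p_c = unname(p_c),
    H_d = binary_entropy(p_d), H_c = binary_entropy(p_c),
    omega = as.numeric(omega), corrected = attr(omega, "corrected"),
    stringsAsFactors = FALSE, row.names = NULL)
  pd <- snp_pair_probabilities(m, "disease", pair_mode, q_mode)
  pc <- snp_pair_probabilities(m, "control", pair_mode, q_mode)
  Om <- snp_odds_ratio(pd$q, pc$q, n_d, n_c)
  infod <- information_content(p_d[c(TRUE, FALSE)], p_d[c(FALSE, TRUE)],
                               pair = pd)
  infoc <- information_content(p_c[c(TRUE, FALSE)], p_c[c(FALSE, TRUE)],
                               pair = pc)
  snp <- data.frame(
    snp_id = pd$snp_id,
    p22_d = pd$p22, p21_d = pd$p21, p11_d = pd$p11, q_d = pd$q,
    p22_c = pc$p22, p21_c = pc$p21, p11_c = pc$p11, q_c = pc$q,
    Omega = as.numeric(Om), Omega_corrected = attr(Om, "corrected"),
    H_snp_d = infod$H_snp, H_snp_c = infoc$H_snp,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(allele = allele, snp = snp, n_d = n_d, n_c = n_c),
            class = "locus_stats")
}

#' @export
print.locus_stats <- function(x, ...) {
  cat("locus_stats:", nrow(x$allele), "allele loci /", nrow(x$snp),
      "SNPs;", x$n_d, "disease,", x$n_c, "control samples\n")
  cat("  allele omega range:",
      sprintf("[%.3g, %.3g]", min(x$allele$omega), max(x$allele$omega)),
      "\n")
  invisible(x)
}

#' Odds-ratio histograms and threshold-set-size curve
#'
#' Histograms (2000 equal-width bins, viewed as densities) of the allele
#' odds ratios omega and SNP odds ratios Omega, plus N(Lambda), the number
#' of allele loci with omega >= Lambda over a threshold grid. The histogram
#' range is clipped at an upper quantile so extreme ratios do not flatten
#' the bins; raw extremes are retained in the result.
#'
#' @param stats a [locus_stats()] object.
#' @param bins number of histogram bins (default 2000).
#' @param Lambda_grid thresholds for N(Lambda); default a 200-point grid
#'   over \[1, 99.9th percentile of omega\].
#' @param clip_quantile upper quantile at which the histogram range is
#'   clipped (default 0.9999).
#' @return An object of class `odds_histogram`: list with `allele` and `snp`
#'   density `data.frame`s (`bin_left`, `bin_right`, `density`),
#'   `N_of_Lambda` (`Lambda`, `N`), and `raw_range` per ratio type.
#' @export
odds_histograms <- function(stats, bins = 2000L, Lambda_grid = NULL,
                            clip_quantile = 0.9999) {
  stopifnot(inherits(stats, "locus_stats"))
  density_table <- function(x) {
    lo <- min(x)
    hi <- as.numeric(stats::quantile(x, clip_quantile))
    if (hi <= lo) hi <- lo + 1
    xx <- pmin(x, hi)
    h <- graphics::hist(xx, breaks = seq(lo, hi, length.out = bins + 1L),
                        plot = FALSE)
    data.frame(bin_left = h$breaks[-length(h$breaks)],
               bin_right = h$breaks[-1L], density = h$density)
  }
  omega <- stats$allele$omega
  Omega <- stats$snp$Omega
  if (is.null(Lambda_grid))
    Lambda_grid <- seq(1, as.numeric(stats::quantile(omega, 0.999)),
                       length.out = 200L)
  N <- vapply(Lambda_grid, function(l) sum(omega >= l), numeric(1))
  structure(list(allele = density_table(omega), snp = density_table(Omega),
                 N_of_Lambda = data.frame(Lambda = Lambda_grid, N = N),
                 raw_range = list(allele = range(omega),
                                  snp = range(Omega))),
            class = "odds_histogram")
}
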