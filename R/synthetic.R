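# Synthetic case/control genotype generator with planted risk loci, plus
# the printed worked-example probability fixture.

#' Specification for synthetic case/control genotype data
#'
#' Describes two cohorts of standard-form sequences: per-locus control
#' probabilities drawn from a null distribution, a minority of planted risk
#' loci with elevated disease-allele odds ratios, and sparse missingness
#' with a few designated high-missingness SNPs. Defaults mirror a typical
#' large case/control SNP panel: cohorts of 919 and 787, mean missingness
#' 0.014%, individual loci up to 10% missing.
#'
#' @param n_cases,n_controls cohort sizes (defaults 919, 787).
#' @param M SNP count (2M allele loci).
#' @param risk_loci `data.frame` with columns `locus` (allele-locus index in
#'   1..2M), `omega` (target allele odds ratio > 0) and optionally
#'   `p_control` (override for the control probability; `NA` keeps the
#'   drawn value). See [risk_on_odd_compartments()].
#' @param null_p function(k) drawing k control probabilities in (0, 1);
#'   default `function(k) rbeta(k, 2, 2)`.
#' @param compartment_mode `"genotypic"` (draw genotype pair categories
#'   consistent with the standard organization, so P(odd = 2) >=
#'   P(even = 2)) or `"independent"` (draw the two compartments
#'   independently; can violate that ordering, useful for fixtures shaped
#'   like published probability tables).
#' @param missing_rate per-genotype missingness probability (default
#'   1.4e-4).
#' @param n_high_missing number of SNPs given elevated missingness.
#' @param high_missing_rate their rate, capped at `max_locus_missing`.
#' @param max_locus_missing cap on any locus missingness (default 0.10).
#' @param seed integer seed; every generation is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cases = 919L, n_controls = 787L, M = 1000L,
                           risk_loci = NULL,
                           null_p = function(k) stats::rbeta(k, 2, 2),
                           compartment_mode = c("genotypic", "independent"),
                           missing_rate = 1.4e-4, n_high_missing = 0L,
                           high_missing_rate = 0.05,
                           max_locus_missing = 0.10, seed = 1L) {
  compartment_mode <- match.arg(compartment_mode)
  stopifnot(n_cases >= 1L, n_controls >= 1L, M >= 1L,
            missing_rate >= 0, missing_rate <= 1,
            high_missing_rate <= max_locus_missing)
  if (!is.null(risk_loci)) {
    stopifnot(is.data.frame(risk_loci),
              all(c("locus", "omega") %in% names(risk_loci)))
    if (anyDuplicated(risk_loci$locus))
      stop("risk locus indices must be distinct")
    if (any(risk_loci$locus < 1L | risk_loci$locus > 2L * M))
      stop("risk locus index outside 1..2M")
    if (any(risk_loci$omega <= 0)) stop("target omega must be > 0")
    if (is.null(risk_loci$p_control)) risk_loci$p_control <- NA_real_
    if (any(!is.na(risk_loci$p_control) &
            (risk_loci$p_control <= 0 | risk_loci$p_control >= 1)))
      stop("risk p_control must lie in (0, 1)")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), M = as.integer(M),
                 risk_loci = risk_loci, null_p = null_p,
                 compartment_mode = compartment_mode,
                 missing_rate = missing_rate,
                 n_high_missing = as.integer(n_high_missing),
                 high_missing_rate = high_missing_rate,
                 max_locus_missing = max_locus_missing,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Place risk loci on odd compartments
#'
#' Convenience constructor for the `risk_loci` table: plants `n_risk` risk
#' loci at the odd compartments of the first `n_risk` SNPs (indices
#' 2k - 1), all at the same target odds ratio. Odd compartments carry the
#' larger control probability under genotypic sampling, so raising the
#' disease probability there never violates the standard-form ordering.
#'
#' @param n_risk number of risk loci.
#' @param omega target allele odds ratio.
#' @param p_control optional fixed control probability (recycled).
#' @return `data.frame` suitable for [synthetic_spec()].
#' @export
risk_on_odd_compartments <- function(n_risk, omega, p_control = NA_real_) {
  data.frame(locus = 2L * seq_len(n_risk) - 1L, omega = omega,
             p_control = p_control)
}

#' Invert the allele odds-ratio relation for the disease probability
#'
#' Given a control probability and a target odds ratio, returns the disease
#' probability p_d such that \[p_d/(1-p_d)\] / \[p_c/(1-p_c)\] = omega.
#'
#' @param p_control control probability in (0, 1).
#' @param omega target odds ratio (> 0).
#' @return Disease probability in (0, 1), vectorized.
#' @examples
#' solve_disease_probability(0.9754, 3.80)  # ~ 0.9934
#' @export
solve_disease_probability <- function(p_control, omega) {
  if (any(p_control <= 0 | p_control >= 1))
    stop("p_control must lie strictly in (0, 1)")
  if (any(omega <= 0)) stop("omega must be > 0")
  od <- omega * p_control / (1 - p_control)
  od / (1 + od)
}

#' Generate synthetic case/control genotype data
#'
#' Draws control compartment probabilities from the spec's null
#' distribution (per SNP, the larger draw is assigned to the odd
#' compartment in genotypic mode), overrides/elevates them at the planted
#' risk loci by inverting the odds-ratio relation, samples sequences, and
#' injects missingness. The planted truth is returned alongside the data.
#'
#' In genotypic mode the SNP genotype law consistent with standard-form
#' margins (p_o, p_e), p_o >= p_e, is p22 = p_e, p21 = p_o - p_e,
#' p11 = 1 - p_o; a single uniform draw per genotype realizes it. In
#' independent mode the two compartments are independent Bernoulli draws.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `matrix` (an [allele_matrix()]), `truth` (per-locus
#'   `data.frame`: `locus`, `locus_id`, `snp_index`, `compartment`,
#'   `p_control`, `p_disease`, `is_risk`, `omega_true`), and `spec`.
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  M <- spec$M
  n_d <- spec$n_cases; n_c <- spec$n_controls
  p <- spec$null_p(2L * M)
  if (any(p <= 0 | p >= 1)) stop("null_p produced values outside (0, 1)")
  oidx <- seq(1L, 2L * M, by = 2L)
  if (spec$compartment_mode == "genotypic") {
    po <- pmax(p[oidx], p[oidx + 1L])
    pe <- pmin(p[oidx], p[oidx + 1L])
    p[oidx] <- po; p[oidx + 1L] <- pe
  }
  p_c <- p
  p_d <- p
  is_risk <- rep(FALSE, 2L * M)
  if (!is.null(spec$risk_loci)) {
    rl <- spec$risk_loci
    override <- !is.na(rl$p_control)
    p_c[rl$locus[override]] <- rl$p_control[override]
    p_d[rl$locus] <- solve_disease_probability(p_c[rl$locus], rl$omega)
    is_risk[rl$locus] <- TRUE
  }
  draw <- function(n, pv) {
    if (spec$compartment_mode == "genotypic") {
      po <- pv[oidx]; pe <- pv[oidx + 1L]
      if (any(po < pe - 1e-12))
        stop("genotypic mode requires p_odd >= p_even at every SNP ",
             "(risk planting on an even compartment can violate this)")
      u <- matrix(stats::runif(n * M), n, M)
      odd <- ifelse(u < rep(po, each = n), 2L, 1L)
      even <- ifelse(u < rep(pe, each = n), 2L, 1L)
    } else {
      odd <- ifelse(matrix(stats::runif(n * M), n, M) <
                      rep(pv[oidx], each = n), 2L, 1L)
      even <- ifelse(matrix(stats::runif(n * M), n, M) <
                       rep(pv[oidx + 1L], each = n), 2L, 1L)
    }
    sym <- matrix(NA_integer_, n, 2L * M)
    sym[, oidx] <- odd
    sym[, oidx + 1L] <- even
    sym
  }
  sym <- rbind(draw(n_d, p_d), draw(n_c, p_c))
  # missingness at the genotype level: both compartments vanish together
  rate <- rep(spec$missing_rate, M)
  if (spec$n_high_missing > 0L) {
    hm <- sample.int(M, min(spec$n_high_missing, M))
    rate[hm] <- min(spec$high_missing_rate, spec$max_locus_missing)
  }
  if (any(rate > 0)) {
    n <- n_d + n_c
    miss <- matrix(stats::runif(n * M), n, M) < rep(rate, each = n)
    sym[, oidx][miss] <- NA_integer_
    sym[, oidx + 1L][miss] <- NA_integer_
  }
  snps <- snp_defs(sprintf("rs%06d", seq_len(M)), chromosome = "1",
                   position = seq_len(M) * 100L,
                   allele1 = "T", allele2 = "A")
  m <- allele_matrix(sym, snps,
                     c(sprintf("case_%04d", seq_len(n_d)),
                       sprintf("ctrl_%04d", seq_len(n_c))),
                     c(rep("disease", n_d), rep("control", n_c)))
  truth <- data.frame(
    locus = seq_len(2L * M), locus_id = m$loci$locus_id,
    snp_index = m$loci$snp_index, compartment = m$loci$compartment,
    p_control = p_c, p_disease = p_d, is_risk = is_risk,
    omega_true = odds(p_d) / odds(p_c),
    stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = m, truth = truth, spec = spec)
}

#' Printed worked-example probability table
#'
#' The six (disease, control) symbol-2 probability pairs of the published
#' three-SNP worked example, as an in-memory fixture for the statistics
#' routines.
#'
#' @return `data.frame` with `snp`, `compartment`, `p_disease`,
#'   `p_control`, one row per allele compartment.
#' @examples
#' tab <- table2_fixture()
#' round(allele_odds_ratio(tab$p_disease, tab$p_control), 2)
#' @export
table2_fixture <- function() {
  data.frame(
    snp = rep(1:3, each = 2L),
    compartment = rep(c("odd", "even"), 3L),
    p_disease = c(0.2302, 0.9934, 0.2329, 0.9947, 0.9987, 0.1105),
    p_control = c(0.2415, 0.9754, 0.2354, 0.9785, 0.9923, 0.1000),
    stringsAsFactors = FALSE)
}
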