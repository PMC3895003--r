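---
title: "Allele-kernel classifier extraction: models, choices and limits"
author: "akernel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-kernel classifier extraction: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akernel)
```

## The problem

Case/control SNP panels record, for each sample, an unordered diploid
genotype at hundreds of thousands of biallelic loci, plus a phenotype label
(disease or control). Conventional association testing ranks individual
SNPs; `akernel` instead treats disease as a weak signal distributed over a
*large* collection of allele-level loci, and extracts a classifier — a set
of loci together with one symbol per locus — that separates the two cohorts
collectively.

## The standard organization

Each SNP genotype is re-encoded as an ordered pair of *allele
compartments*. The two alleles of a SNP are ranked by a fixed nucleotide
alias (A=1, C=2, G=3, T=4; only the within-SNP ranking matters, and the map
is frozen in `NUCLEOTIDE_ALIAS`), and the genotype is written high-allele
first. Re-aliasing by 2 (high) and 1 (low) turns each SNP into an odd and
an even column of a samples x 2M symbol matrix: heterozygotes always encode
(2,1), homozygotes (2,2) or (1,1). No information is lost — the SNP
definitions invert the encoding — and the two binary compartments together
always carry at least as much entropy as the three-category SNP genotype
(`information_content()`; the inequality is exact because the SNP form
merges categories).

Cleaning follows two rules: SNPs with more than 2 missing symbols over all
samples are dropped entirely (`filter_missing_loci()`), and the few
remaining gaps are filled with the column's modal symbol computed over both
cohorts pooled (`impute_modal()`). Pooling avoids leaking labels into the
genotypes; an exact 50/50 tie imputes symbol 2 — deterministic, and a
measure-zero event in real data.

A consequence of the encoding worth flagging: in encoder output
P(odd = 2) >= P(even = 2) at every SNP, because heterozygotes write their 2
to the odd column. Published probability tables for this organization do
not always satisfy that constraint (acquisition-ordered compartments would
not), so none of the statistics routines assume it, and the simulator
offers an `independent` compartment mode that can violate it.

## Locus statistics

For each compartment and cohort, `locus_stats()` computes the symbol-2
frequency p, and the allele odds ratio

omega = [p_d / (1 - p_d)] / [p_c / (1 - p_c)].

A zero cell (p in {0, 1}) would make omega infinite; the Haldane–Anscombe
correction (0.5 added to each of the four implied counts) is applied only
to such loci, which are flagged. At the SNP level the genotype-pair
probabilities (p22, p21, p11) are counted directly, and the SNP odds ratio
Omega is the same form applied to a SNP-level probability q.

**Choice of q.** Three definitions are available. The default is
q = p22, the homozygous-22 probability (the independence product p_o·p_e):
under it, a risk SNP whose informative compartment sits near probability 1
in both cohorts has Omega collapsing to the *uninformative* compartment's
ratio, i.e. near 1 — exactly the contrast that makes allele-level screening
more sensitive than SNP-level screening. The alternatives
(`q_mode = "carrier"`, q = p22 + p21, and `"allele_freq"`,
q = (p_o + p_e)/2) are kept because the SNP-level definition is genuinely
underdetermined; the carrier form compounds both compartment ratios
(1 - q = (1-p_o)(1-p_e)) and therefore does not show the near-unity
behaviour, which is why it is not the default.

`odds_histograms()` bins omega and Omega into 2000 equal-width bins viewed
as densities (range clipped at the 99.99th percentile so a handful of
extreme ratios cannot flatten the grid; raw extremes are kept in the
result) and tabulates N(Lambda), the number of allele loci with
omega >= Lambda.

## The modal classifier and its evaluation

`select_high_value()` keeps loci with omega >= Lambda (one-sided default;
a two-sided option uses max(omega, 1/omega) and assigns the enriched
symbol). Selections are nested in Lambda. The *mode word*
(`mode_word()`) takes the disease-cohort modal symbol at each selected
locus; a sample's *score* (`score_sequences()`) is the number of selected
loci where it agrees with the word — identically L minus the Hamming
distance between the projected sequence and the word.

Scores are sums over many loci, so each cohort's score distribution is
summarized by a normal fit (mean, unbiased SD). `roc_error()` minimizes
the gaussian error fraction

E(Delta) = [n_d (1 - T(Delta)) + n_c FP(Delta)] / (n_d + n_c)

over a 1e4-point grid spanning both means +/- 4 SD. Grid search replaces
the classical slope -1 ROC tangency characterization because the tangency
statement depends on the cohort-size ratio; for n_d = n_c they coincide.
Ties at the threshold classify as disease (conservative for screening).
The empirical misclassification counts at Delta* are reported alongside
the gaussian prediction; empirically the realized error tends to sit
*above* the gaussian estimate, because scores are Poisson-binomial sums
whose tails are heavier on the side toward the other cohort. This
matters quantitatively: when the predicted E_min falls below 1/(3n) the
comparison "empirical error <= 3 E_min" degenerates into requiring zero
realized errors, and a single tail sample decides it — a discreteness
limit of error-rate checks at desk-scale n, not a property of the method.

`sweet_spot()` reports plateaus of N(Lambda) (relative change below 1%
over a window of width 0.1 by default): thresholds where the selection
size is insensitive to the exact cutoff. `score_scaling_table()` exposes
(L, mu, sigma, Delta*, E_min) as functions of Lambda for users who want to
fit scalings; the package asserts no functional form for them.

## The indicator vector

The mode word only records *which* symbol is more probable. The indicator
vector refines it: sequences restricted to the selected loci are embedded
in Euclidean space by symbol 2 -> +1, symbol 1 -> -1, so squared Euclidean
distance is exactly `EMBED_HAMMING_FACTOR` (= 4) times Hamming distance
(an orthonormal-pair embedding with constant 2 could be swapped in; the
constant is tested, not assumed). With D and C the embedded cohort
matrices, the indicator v maximizes the mean-squared-projection contrast

(1/n_d) sum_d (x . v)^2 - (1/n_c) sum_c (x . v)^2, ||v|| = 1,

i.e. v is the leading eigenvector of K = D'D/n_d - C'C/n_c. For
L >> n the eigenproblem is solved in the span of the data rows (the method
of snapshots): with X the stacked data and W = diag(+1/n_d, -1/n_c), the
n x n problem W X X' a = lambda a is solved and v = X'a. W is indefinite,
so the small problem is nonsymmetric; the returned eigenpair's residual is
verified against 1e-8, the dense L x L path is used when L <= n, and the
two paths agree to 1e-8 in the eigenvalue on random instances (tested).
The sign of v is fixed by alignment with mean(D) - mean(C). If no positive
eigenvalue exists the solver warns rather than fails (that happens exactly
when no direction separates the cohorts, e.g. D = C).

One property of this criterion deserves emphasis: on +/-1 data every
single coordinate direction has squared projection exactly 1 in both
cohorts, so a *lone* disease-biased locus contributes nothing — the
criterion detects loci whose biases co-occur across the disease cohort,
through their cross-products. That is the intended regime (a large shared
kernel of loci), but it means the indicator vector is not a single-marker
test and should not be read as one.

**Pseudo-probabilities.** Components are rescaled by the largest absolute
component, v' = v / max|v|, and mapped to p* = (1 + v')/2, the
probability-like weight of symbol 2. Loci with max(p*, 1 - p*) > theta are
retained (theta default 0.5; retention is monotone in theta). A diagnostic
unnormalized value on the root-mean-square component scale
(v / sqrt(1/L)) is reported as well; it can exceed 1 or drop below 0,
which is precisely the "overprobable" behaviour the retention rule
exploits — the max-normalized p* cannot, by construction.

## Structure matrices

`hamming_matrix()` computes all intra-cohort pairwise Hamming distances on
the selected loci (with the upper-triangle histogram and its gaussian
fit), and `reorder_by_mean_distance()` permutes samples by ascending mean
distance to all others. The mean excludes the self term; including it
would shift every mean equally at fixed n, leaving the ordering unchanged.
Ties keep their current relative order, making the reordering idempotent.
`reordered_scores()` lists scores in that order; points are dropped from
the trace only on explicit request — no automatic outlier removal. No
clustering or sub-type calling is attempted: the reordered heatmap
(optionally exported as plain PGM) is a visualization, and any apparent
granularity is left to the user's judgement.

## Validation procedures

*Permutation trials* (`permutation_trials()`): labels are permuted with
cohort sizes fixed — the only randomization that preserves every genotype
statistic — the classifier is recomputed at the same Lambda, and the
fraction of reference loci recovered *with matching symbol* is recorded.
Symbol-matched overlap is the right bookkeeping because a permuted
classifier can differ by symbol change, by a major locus dropping out, or
by a minor locus entering; modelling those as three independent fair binary
alterations gives a survival probability of 1/8 per locus
(`alteration_overlap_simulation()` provides that baseline by direct
simulation).

*Random baselines* (`random_baseline()`): drawing the same number of loci
uniformly without replacement gives expected locus overlap L/2M
(hypergeometric); with modal symbols the symbol always matches on the
intersection, with random symbols the matched overlap halves.

*Train/test split* (`split_validate()`): selection, word and threshold are
computed on the training split only, and test samples are scored at the
training Delta*. Selecting loci on the full data is allowed for
diagnostics but warns: it invalidates the test error as a measure of
prediction.

*Reduced classifier* (`reduced_classifier_prediction()`): per trial, one
disease and one control sample are held out, the classifier is recomputed,
its loci are ranked by the disease-minus-control frequency difference of
the classifier symbol, only the bottom-ranked n_bottom are kept, and the
trial is correct when the held-out disease sample outscores the held-out
control. The rate over trials comes with an exact binomial p-value against
1/2. The operation reports rates without interpreting why bottom-ranked
loci might carry predictive advantage.

*Subsample extrapolation* (`subsample_extrapolation()`): both cohorts are
subsampled at fractions (60%...100% by default), the selection size is
averaged per fraction, and L(n) = L_inf + beta/n is fit by least squares.
The 1/n form is chosen because the excess selection at finite n comes from
frequency-estimation noise pushing null loci over the threshold, which
shrinks with sample size and must leave a finite asymptote; L_inf
estimates the selection size under unbounded data. At 100% the subsample
is the full data, so the curve's endpoint equals the reference selection
exactly.

All stochastic operations take an explicit integer seed and are
bit-reproducible from it.

## The synthetic generator

`generate_genotypes()` emulates the statistical shape of a large
case/control panel: two cohorts (defaults 919 cases / 787 controls),
per-locus control probabilities drawn from Beta(2, 2) (a unimodal,
boundary-avoiding null for symbol frequencies), a minority of planted risk
loci whose disease probability is obtained by inverting the odds-ratio
relation at a target omega, sparse missingness (mean 0.014% per genotype,
with a configurable handful of SNPs up to 10% to exercise the cleaning
rules), and loci independent of one another. In `genotypic` mode the SNP
genotype law consistent with standard-form margins (p_o >= p_e) is
p22 = p_e, p21 = p_o - p_e, p11 = 1 - p_o, realized by one uniform draw
per genotype; per SNP the larger of the two drawn probabilities is
assigned to the odd compartment, and the default risk placement
(`risk_on_odd_compartments()`) targets odd compartments so planting can
never violate the margin ordering. The `independent` mode draws the two
compartments independently for fixtures that break the encoder constraint
on purpose.

What the simulator does *not* model: linkage disequilibrium (all loci are
independent, matching the analysis model's own assumption), haplotype
blocks, population stratification, relatedness, genotyping batch effects.
Passing tests on this generator therefore demonstrates correctness of the
algorithms under the stated model, not robustness of the method to the
correlation structure of real panels.

## Problem sizes and numerical choices

The test suite runs the full pipeline at moderate sizes (hundreds of
samples, hundreds of SNPs) and one larger recovery study at 900/800
samples and 5200 SNPs with 200 planted risk loci at omega = 4 — sizes
chosen so that planted-truth recovery, error calibration and subsample
extrapolation are all exercised at meaningful signal-to-noise on a
desktop. Tolerances follow the source of error: exact identities at
1e-12, eigen-solver agreement at 1e-8/1e-6, stochastic checks at 3-4
standard errors of the relevant estimator. Degenerate inputs (constant
scores, identical cohorts, all-missing columns, empty selections) are
either flagged with warnings or rejected with informative errors, as
documented per function.

## Known limitations

- The indicator-vector criterion is blind to isolated single-locus effects
  on +/-1 data (see above); it is a collective detector by design.
- The SNP-level q is underdetermined; three definitions are provided and
  the default is the one that preserves the allele-vs-SNP sensitivity
  contrast.
- Gaussian error estimates understate realized tail errors for strongly
  separated cohorts; at small n the empirical error comparison is
  discreteness-limited (see the ROC section).
- Odds ratios at boundary frequencies depend on the continuity correction;
  corrected loci are flagged so downstream users can exclude them.
- The PLINK reader infers each SNP's alleles from the letters observed in
  the file; monomorphic-in-file SNPs are skipped with a warning since
  their second allele is unknowable from the .ped alone.
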