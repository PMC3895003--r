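# akernel — allele-kernel classifier extraction for case/control SNP data

`akernel` extracts a large, collective genomic classifier of disease risk
from case/control SNP genotype panels. It is aimed at researchers who have
a diploid genotype matrix (VCF, PLINK `.ped/.map`, or the package's
standard-form TSV) with a disease/control label per sample, and who want to
screen, build, evaluate and stress-test an allele-level classifier without
committing to single-marker association statistics.

## The method

1. **Standard organization.** Each biallelic SNP genotype is rewritten as
   an ordered pair of allele compartments (odd, even), high-ranked allele
   first, aliased 2/1. A heterozygote is always `(2,1)`, homozygotes are
   `(2,2)` / `(1,1)`. SNPs with more than 2 missing symbols over all
   samples are dropped; remaining gaps take the pooled column mode.
2. **Allele-level screening.** For each compartment, the disease/control
   odds ratio of the symbol-2 frequency,
   `omega = [p_d/(1-p_d)] / [p_c/(1-p_c)]`,
   is computed (Haldane–Anscombe correction at zero cells). Loci with
   `omega >= Lambda` form the classifier subspace; the two-compartment form
   carries more information than the SNP genotype (`H_o + H_e >= H_snp`),
   which is why screening happens at the allele level.
3. **Classifier.** The *mode word* takes the disease modal symbol at each
   selected locus. A sample's *score* is its agreement count with the word
   (= `L` minus Hamming distance). Cohort score distributions are fit by
   gaussians and an ROC grid search yields the decision threshold `Delta*`
   and minimum error fraction `E_min`. A refinement embeds sequences as
   ±1 vectors and maximizes the contrast
   `(1/n_d) Σ_d (x·v)² − (1/n_c) Σ_c (x·v)²`, `‖v‖ = 1` — the leading
   eigenvector of `D'D/n_d − C'C/n_c`, solved in sample space by the
   method of snapshots — then retains the "overprobable" loci via
   pseudo-probabilities `(1 + v/max|v|)/2`.
4. **Structure and validation.** Intra-cohort Hamming structure matrices
   (reordered by mean distance), phenotype-permutation overlap trials,
   random-locus baselines, train/test splits, leave-two-out reduced
   classifiers, and subsample extrapolation `L(n) = L_inf + beta/n` of the
   selection size.

A synthetic generator (`synthetic_spec()` / `generate_genotypes()`) plants
risk loci at known odds ratios so the whole pipeline is testable end to end
with known truth.

## Worked example

```r
library(akernel)

sim <- generate_genotypes(synthetic_spec(
  n_cases = 300, n_controls = 260, M = 1000,
  risk_loci = risk_on_odd_compartments(50, omega = 4),
  n_high_missing = 3, seed = 7))
m <- impute_modal(filter_missing_loci(sim$matrix, max_missing = 2))
m
#> allele_matrix: 560 samples x 1986 allele loci ( 993 SNPs )
#>   cohorts: 300 disease / 260 control
#>   missing entries: 0 (0%)
```

Seven of the 1000 simulated SNPs exceeded the missingness rule and were
dropped (1986 = 2 x 993 allele loci remain). Screen and classify:

```r
st  <- locus_stats(m)
sel <- select_high_value(st, Lambda = 2.4)
sel
#> locus_selection: L = 51 allele loci at Lambda = 2.4 (one-sided)

w     <- mode_word(m, sel)
sc    <- score_sequences(m, w)
fit   <- fit_gaussians(sc$score[sc$label == "disease"],
                       sc$score[sc$label == "control"])
model <- roc_error(fit, scores = sc)
model
#> score_model: Delta* = 38.438  E_min = 0.01785
#>   gaussian fits: disease N( 43.5533 , 2.328 )  control N( 32.3962 , 3.008 )
#>   empirical at Delta*: 2 FN + 7 FP ( error fraction 0.01607 )
```

51 loci pass the threshold (the 50 planted risk loci plus sampling-noise
entries). The cohorts' score gaussians sit ~11 points apart, the gaussian
model predicts a 1.8% minimum error, and applying `Delta*` to the actual
scores misclassifies 9 of 560 samples. Validation:

```r
permutation_trials(m, Lambda = 2.4, n_trials = 50, seed = 17)
#> randomization_report (permuted-labels): 50 trials, L_ref = 51
#>   overlap fraction: mean 0.007843  sd 0.0105

subsample_extrapolation(m, Lambda = 2.4, n_repeats = 5, seed = 17)
#> subsample_curve: L(n) = L_inf + beta/n fit at Lambda = 2.4
#>   L_inf = 46.3995  beta = 2584.98  max rel residual = 0.00761
```

Permuting the labels destroys the classifier (mean symbol-matched overlap
0.8%, versus 100% for the true labels), and extrapolating the selection
size to unbounded data gives ~46 loci — close to the 50 planted, the
excess at finite n being frequency noise.

The same pipeline is scriptable from a shell via the thin CLI wrapper:

```sh
AK=$(Rscript -e 'cat(system.file("cli", "akernel", package = "akernel"))')
Rscript $AK simulate --n-risk 50 --risk-omega 4 --seed 7 --out-prefix sim
Rscript $AK classify --std sim_std.tsv --pheno sim_pheno.tsv \
        --Lambda 2.4 --out-prefix model
```

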