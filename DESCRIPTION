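Package: akernel
Title: Allele-Kernel Classifier Extraction for Case/Control SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts large genomic classifiers of disease risk from
    case/control SNP genotype matrices. Re-encodes diploid genotypes into a
    standard organization of odd/even allele compartments aliased 2/1,
    screens loci by allele-level odds ratios, builds modal-word and
    eigen-optimized indicator-vector classifiers via the method of
    snapshots, evaluates them with agreement scores, gaussian fits and ROC
    error analysis, computes Hamming structure matrices, and validates by
    phenotype permutation, random baselines, train/test splits,
    leave-two-out reduced classifiers and subsample-size extrapolation.
    Includes a synthetic genotype simulator with planted risk loci so the
    whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
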