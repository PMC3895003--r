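# Permutation trials, random baselines, splits, reduced classifiers,
# subsample extrapolation.

test_that("the reference classifier overlaps itself fully", {
  sim <- signal_sim()
  m <- sim$matrix
  # a no-op 'permutation' is the identity: recomputing at the same labels
  # must reproduce the classifier, so overlap is exactly 1
  st <- locus_stats(m)
  sel <- select_high_value(st, 2.4)
  w <- mode_word(m, sel)
  ref <- list(loci = sel$loci, word = w$word)
  expect_equal(akernel:::overlap_fraction(ref, ref), 1)
})

test_that("permutation trials are reproducible and size-preserving", {
  sim <- signal_sim(n_cases = 60, n_controls = 50, M = 120, n_risk = 15,
                    seed = 31)
  m <- sim$matrix
  r1 <- permutation_trials(m, 2.4, n_trials = 8, seed = 5)
  r2 <- permutation_trials(m, 2.4, n_trials = 8, seed = 5)
  expect_identical(r1$overlap_fractions, r2$overlap_fractions)
  r3 <- permutation_trials(m, 2.4, n_trials = 8, seed = 6)
  expect_false(identical(r1$overlap_fractions, r3$overlap_fractions))
  expect_true(all(r1$overlap_fractions >= 0 & r1$overlap_fractions <= 1))
  expect_error(permutation_trials(m, 2.4, n_trials = 0), "n_trials")
})

test_that("alteration model yields 1/8 survival", {
  r <- alteration_overlap_simulation(2000, n_trials = 50, seed = 3)
  se <- sqrt(0.125 * 0.875 / (2000 * 50))
  expect_lt(abs(r$mean - 0.125), 4 * se)
})

test_that("random-locus baselines match hypergeometric expectations", {
  sim <- signal_sim(n_cases = 80, n_controls = 70, M = 300, n_risk = 40,
                    omega = 8, seed = 33)
  m <- sim$matrix
  st <- locus_stats(m)
  L <- select_high_value(st, 2.4)$L
  twoM <- ncol(m$symbols)
  rb <- random_baseline(m, 2.4, "random-loci-modal", n_trials = 400,
                        seed = 7)
  exp_frac <- L / twoM
  se <- sqrt(exp_frac * (1 - exp_frac) / (L * 400))
  expect_lt(abs(rb$mean - exp_frac), 4 * se)
  # random symbols roughly halve the matched overlap
  rs <- random_baseline(m, 2.4, "random-loci-random-symbol",
                        n_trials = 400, seed = 7)
  expect_lt(rs$mean, rb$mean)
  expect_equal(rs$mean / exp_frac, 0.5, tolerance = 0.35)
})

test_that("train/test split behaves on signal, null and copy data", {
  sim <- signal_sim(n_cases = 200, n_controls = 180, M = 300, n_risk = 30,
                    omega = 6, seed = 35)
  sv <- split_validate(sim$matrix, 2.4, train_fraction = 0.85, seed = 1)
  expect_lt(sv$test_error, 0.5)
  expect_lte(sv$test_error, max(3 * sv$E_min, 0.15))
  # selecting on the full data warns
  expect_warning(split_validate(sim$matrix, 2.4, seed = 1,
                                select_on = "full"),
                 "not a .* measure of prediction|full data")
  # null data: test error near 1/2
  nul <- null_sim(n_cases = 120, n_controls = 120, M = 200, seed = 36)
  sv0 <- split_validate(nul$matrix, 1.8, train_fraction = 0.7, seed = 2)
  expect_gt(sv0$test_error, 0.25)
  expect_error(split_validate(sim$matrix, 2.4, train_fraction = 0.999),
               "split")
})

test_that("train on data, test on identical copy gives equal errors", {
  sim <- signal_sim(n_cases = 60, n_controls = 60, M = 150, n_risk = 20,
                    seed = 37)
  m <- sim$matrix
  # duplicate every sample; split so train indices and test indices hold
  # identical sequence sets
  sym2 <- rbind(m$symbols[m$labels == "disease", ],
                m$symbols[m$labels == "disease", ],
                m$symbols[m$labels == "control", ],
                m$symbols[m$labels == "control", ])
  m2 <- fixture_matrix(sym2, c(rep("disease", 120), rep("control", 120)))
  sv <- split_validate(m2, 2.4, train_sizes = c(60, 60), seed = 4)
  # train cohort and test cohort are drawn from identical duplicated pools,
  # so the two error rates agree closely
  expect_lt(abs(sv$train_error - sv$test_error), 0.1)
})

test_that("reduced bottom-ranked classifier predicts planted signal", {
  sim <- signal_sim(n_cases = 120, n_controls = 110, M = 150, n_risk = 30,
                    omega = 8, seed = 39)
  r <- reduced_classifier_prediction(sim$matrix, 2.4, n_bottom = 10,
                                     n_trials = 60, seed = 2)
  expect_gt(r$rate, 0.5)
  expect_lt(r$p_value, 0.05)
  # null data: rate within the binomial band around 1/2
  nul <- null_sim(n_cases = 80, n_controls = 80, M = 120, seed = 40)
  r0 <- reduced_classifier_prediction(nul$matrix, 1.5, n_bottom = 3,
                                      n_trials = 60, seed = 3)
  expect_lt(abs(r0$rate - 0.5), 2.6 * sqrt(0.25 / 60))
  expect_error(
    reduced_classifier_prediction(sim$matrix, 2.4, n_bottom = 10,
                                  n_trials = 0), "n_trials")
})

test_that("subsample extrapolation fits L_inf + beta/n", {
  # deterministic selection size independent of n: beta ~ 0, L_inf ~ L
  sim <- signal_sim(n_cases = 150, n_controls = 150, M = 100, n_risk = 20,
                    omega = 30, seed = 41)
  sub <- subsample_extrapolation(sim$matrix, 2.4, n_repeats = 3, seed = 5)
  L100 <- sub$table$mean_L[sub$table$fraction == 1]
  expect_lt(abs(sub$L_inf - L100) / L100, 0.3)
  expect_lt(sub$max_rel_residual, 0.1)
  # 100% subsample equals the reference selection exactly
  st <- locus_stats(sim$matrix)
  expect_equal(L100, select_high_value(st, 2.4)$L)
  expect_error(subsample_extrapolation(sim$matrix, 2.4,
                                       fractions = c(0, 0.5)),
               "fractions")
  # reproducibility
  sub2 <- subsample_extrapolation(sim$matrix, 2.4, n_repeats = 3, seed = 5)
  expect_identical(sub$table, sub2$table)
})
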