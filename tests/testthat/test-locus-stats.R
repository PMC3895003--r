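# Probabilities, entropies, allele and SNP odds ratios, histograms.

test_that("compartment and pair probabilities match direct counting", {
  # 6 samples, 1 SNP with pairs {22 x3, 21 x2, 11 x1}
  sym <- cbind(c(2L, 2L, 2L, 2L, 2L, 1L), c(2L, 2L, 2L, 1L, 1L, 1L))
  m <- fixture_matrix(sym, rep("disease", 6))
  expect_equal(unname(compartment_probabilities(m, "disease")),
               c(5 / 6, 0.5))
  pp <- snp_pair_probabilities(m, "disease")
  expect_equal(pp$p22, 0.5)
  expect_equal(pp$p21, 1 / 3)
  expect_equal(pp$p11, 1 / 6)
  expect_equal(pp$q, 0.5)  # q = p22 under the default definition
  expect_equal(snp_pair_probabilities(m, "disease",
                                      q_mode = "carrier")$q, 5 / 6)
  expect_equal(snp_pair_probabilities(m, "disease",
                                      q_mode = "allele_freq")$q,
               (5 / 6 + 0.5) / 2)
  expect_equal(pp$p22 + pp$p21 + pp$p11, 1, tolerance = 1e-12)
  # trivial columns
  m2 <- fixture_matrix(cbind(rep(2L, 10), rep(c(2L, 1L), 5)),
                       rep("disease", 10))
  expect_equal(unname(compartment_probabilities(m2, "disease")),
               c(1, 0.5))
  expect_error(compartment_probabilities(m2, "control"), "empty cohort")
})

test_that("allele odds ratio reproduces the printed worked example", {
  tab <- table2_fixture()
  w <- allele_odds_ratio(tab$p_disease, tab$p_control)
  expect_equal(round(as.numeric(w), 2)[c(1, 2, 4, 5)],
               c(0.94, 3.80, 4.13, 5.96), tolerance = 0.011)
  expect_equal(round(as.numeric(w[3]), 4), 0.9862)
  expect_equal(round(as.numeric(w[6]), 3), 1.118)
  expect_equal(as.numeric(allele_odds_ratio(0.3, 0.3)), 1)
  expect_error(allele_odds_ratio(1.2, 0.5), "0, 1")
})

test_that("near-unity probabilities give omega ~ eps_c / eps_d", {
  eps_d <- 1e-4; eps_c <- 2e-4
  w <- as.numeric(allele_odds_ratio(1 - eps_d, 1 - eps_c))
  expect_equal(w, eps_c / eps_d, tolerance = 1e-3)
})

test_that("boundary probabilities use the Haldane correction when sized", {
  w <- allele_odds_ratio(1, 0.9, n_d = 100, n_c = 100)
  expect_true(is.finite(as.numeric(w)))
  expect_true(attr(w, "corrected"))
  expect_equal(as.numeric(w),
               (100.5 / 0.5) / (90.5 / 10.5))
  expect_warning(allele_odds_ratio(1, 0.9), "cohort sizes")
})

test_that("omega from counts equals omega from probabilities", {
  set.seed(5)
  n_d <- 37; n_c <- 29
  x_d <- sample(1:(n_d - 1), 50, replace = TRUE)
  x_c <- sample(1:(n_c - 1), 50, replace = TRUE)
  w_counts <- (x_d / (n_d - x_d)) / (x_c / (n_c - x_c))
  w_prob <- as.numeric(allele_odds_ratio(x_d / n_d, x_c / n_c))
  expect_equal(w_prob, w_counts, tolerance = 1e-12)
})

test_that("omega obeys label symmetry and monotonicity", {
  set.seed(6)
  p_d <- runif(30, 0.05, 0.95); p_c <- runif(30, 0.05, 0.95)
  w <- as.numeric(allele_odds_ratio(p_d, p_c))
  w_swap <- as.numeric(allele_odds_ratio(1 - p_d, 1 - p_c))
  expect_equal(w_swap, 1 / w, tolerance = 1e-12)
  # increasing p_d with p_c fixed strictly increases omega
  p_grid <- seq(0.1, 0.9, by = 0.1)
  w_grid <- as.numeric(allele_odds_ratio(p_grid, rep(0.4, 9)))
  expect_true(all(diff(w_grid) > 0))
})

test_that("SNP odds ratio stays near 1 where allele omega is large", {
  tab <- table2_fixture()
  # build a two-cohort fixture at the printed probabilities
  # (independent-compartment simulator, large n, fixed seed)
  M <- 3L
  spec <- synthetic_spec(
    n_cases = 4000, n_controls = 4000, M = M,
    compartment_mode = "independent", missing_rate = 0, seed = 9)
  sim <- generate_genotypes(spec)
  m <- sim$matrix
  # overwrite symbols with draws at the printed probabilities
  set.seed(10)
  for (j in 1:6) {
    m$symbols[m$labels == "disease", j] <-
      ifelse(runif(4000) < tab$p_disease[j], 2L, 1L)
    m$symbols[m$labels == "control", j] <-
      ifelse(runif(4000) < tab$p_control[j], 2L, 1L)
  }
  st <- locus_stats(m)
  # at the two bold-valued SNPs the allele channel dominates the SNP one
  for (k in c(1L, 2L)) {
    w_max <- max(st$allele$omega[st$allele$snp_index == k])
    expect_gt(w_max, st$snp$Omega[k])
  }
  expect_equal(st$snp$Omega, rep(1, 3), tolerance = 0.35)
  # q_d = q_c gives Omega exactly 1; hand fixture 0.6/0.5 gives 1.5
  expect_equal(as.numeric(snp_odds_ratio(0.7, 0.7)), 1)
  expect_equal(as.numeric(snp_odds_ratio(0.6, 0.5)), 1.5)
})

test_that("entropies behave and the information inequality holds", {
  expect_equal(information_content(0.5, 0.5)$H_o, 1)
  expect_equal(information_content(0, 1)$H_o, 0)
  expect_equal(information_content(0, 1)$H_e, 0)
  grid <- expand.grid(p_o = seq(0.05, 0.95, by = 0.05),
                      p_e = seq(0.05, 0.95, by = 0.05))
  ic <- information_content(grid$p_o, grid$p_e)
  expect_true(all(ic$H_o + ic$H_e >= ic$H_snp - 1e-12))
  expect_true(all(ic$H_o <= 1 + 1e-12 & ic$H_e <= 1 + 1e-12))
})

test_that("odds histograms integrate to 1 and N(Lambda) is non-increasing", {
  sim <- signal_sim()
  st <- locus_stats(sim$matrix)
  hg <- odds_histograms(st, bins = 500)
  width_a <- hg$allele$bin_right - hg$allele$bin_left
  expect_equal(sum(hg$allele$density * width_a), 1, tolerance = 1e-8)
  width_s <- hg$snp$bin_right - hg$snp$bin_left
  expect_equal(sum(hg$snp$density * width_s), 1, tolerance = 1e-8)
  expect_true(all(diff(hg$N_of_Lambda$N) <= 0))
})

test_that("null data concentrates omega near 1", {
  sim <- null_sim(n_cases = 200, n_controls = 200, M = 400, seed = 21)
  st <- locus_stats(sim$matrix)
  expect_lt(abs(median(st$allele$omega) - 1), 0.1)
  expect_lt(mean(st$allele$omega >= 2.4), 0.02)
})
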