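# Euclidean embedding, the snapshot eigenproblem, pseudo-probabilities.

test_that("embedding ties squared Euclidean to Hamming distance", {
  set.seed(12)
  sym <- matrix(sample(c(1L, 2L), 6 * 20, replace = TRUE), 6, 20)
  m <- fixture_matrix(sym, rep(c("disease", "control"), each = 3))
  E <- embed_cohorts(m)
  expect_true(all(E$D %in% c(-1, 1)))
  # identical sequences -> distance 0
  expect_equal(sum((E$D[1, ] - E$D[1, ])^2), 0)
  # sequences differing at k loci -> squared distance 4k
  for (i in 2:3) {
    hd <- sum(sym[1, ] != sym[i, ])
    expect_equal(sum((E$D[1, ] - E$D[i, ])^2), EMBED_HAMMING_FACTOR * hd)
  }
  # cohort mean at a locus with p = P(symbol 2) is 2p - 1
  p <- colMeans(sym[1:3, ] == 2L)
  expect_equal(colMeans(E$D), 2 * p - 1, ignore_attr = TRUE)
})

test_that("snapshot solution matches the dense eigendecomposition", {
  set.seed(13)
  for (r in 1:20) {
    n_d <- sample(3:25, 1); n_c <- sample(3:25, 1)
    L <- sample((n_d + n_c + 1):200, 1)
    sym <- matrix(sample(c(1L, 2L), (n_d + n_c) * L, replace = TRUE),
                  n_d + n_c, L)
    D <- 2 * sym[seq_len(n_d), , drop = FALSE] - 3
    C <- 2 * sym[n_d + seq_len(n_c), , drop = FALSE] - 3
    E <- structure(list(D = D, C = C, selection = NULL,
                        loci = seq_len(L),
                        locus_id = as.character(seq_len(L))),
                   class = "embedded_cohort")
    snap <- solve_indicator(E, method = "snapshot")
    K <- crossprod(D) / n_d - crossprod(C) / n_c
    eg <- eigen(K, symmetric = TRUE)
    lam_ref <- eg$values[1]
    v_ref <- eg$vectors[, 1]
    if (sum(v_ref * snap$v) < 0) v_ref <- -v_ref
    expect_equal(snap$lambda, lam_ref, tolerance = 1e-8)
    expect_lt(max(abs(snap$v - v_ref)), 1e-6)
  }
})

test_that("identical cohorts give a zero operator with a warning", {
  set.seed(16)
  base <- matrix(sample(c(1L, 2L), 3 * 30, replace = TRUE), 3, 30)
  m <- fixture_matrix(rbind(base, base),
                      rep(c("disease", "control"), each = 3))
  E <- embed_cohorts(m)
  expect_warning(iv <- solve_indicator(E, method = "direct"),
                 "no positive eigenvalue")
  expect_equal(iv$lambda, 0, tolerance = 1e-10)
})

test_that("a planted disease-biased block dominates the indicator", {
  # the criterion contrasts second moments of +/-1 data, so a lone biased
  # locus carries no signal (its squared projection is 1 in both cohorts);
  # a block of jointly biased loci does, via their cross-products
  set.seed(14)
  n <- 60; L <- 30; block <- 1:6
  sym <- matrix(sample(c(1L, 2L), 2 * n * L, replace = TRUE), 2 * n, L)
  sym[seq_len(n), block] <-
    ifelse(matrix(runif(n * 6), n, 6) < 0.9, 2L, 1L)
  m <- fixture_matrix(sym, rep(c("disease", "control"), each = n))
  iv <- solve_indicator(embed_cohorts(m))
  expect_setequal(order(abs(iv$v), decreasing = TRUE)[1:6], block)
  expect_gt(iv$lambda, 0)
  # sign convention: aligned with mean(D) - mean(C)
  E <- embed_cohorts(m)
  expect_gte(sum(iv$v * (colMeans(E$D) - colMeans(E$C))), 0)
})

test_that("label swap negates the criterion spectrum", {
  set.seed(15)
  sym <- matrix(sample(c(1L, 2L), 24 * 40, replace = TRUE), 24, 40)
  m1 <- fixture_matrix(sym, rep(c("disease", "control"), each = 12))
  m2 <- fixture_matrix(sym, rep(c("control", "disease"), each = 12))
  E1 <- embed_cohorts(m1); E2 <- embed_cohorts(m2)
  K1 <- crossprod(E1$D) / 12 - crossprod(E1$C) / 12
  K2 <- crossprod(E2$D) / 12 - crossprod(E2$C) / 12
  ev1 <- eigen(K1, symmetric = TRUE, only.values = TRUE)$values
  ev2 <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(ev2), -min(ev1), tolerance = 1e-10)
  # the solver's leading eigenvalue agrees with the dense spectrum
  iv <- solve_indicator(E1, method = "direct")
  expect_equal(iv$lambda, max(ev1), tolerance = 1e-10)
})

test_that("indicator criterion beats the embedded modal word", {
  sim <- signal_sim()
  m <- sim$matrix
  st <- locus_stats(m)
  sel <- select_high_value(st, 2.4)
  E <- embed_cohorts(m, sel)
  iv <- solve_indicator(E)
  w <- mode_word(m, sel)
  v_word <- 2 * w$word - 3
  expect_gte(criterion_value(E, iv$v) + 1e-10,
             criterion_value(E, v_word))
  expect_equal(sum(iv$v^2), 1, tolerance = 1e-10)
})

test_that("pseudo-probability retention is monotone in theta", {
  sim <- signal_sim()
  st <- locus_stats(sim$matrix)
  sel <- select_high_value(st, 2.4)
  iv <- solve_indicator(embed_cohorts(sim$matrix, sel))
  r1 <- pseudo_probabilities(iv, 0.5)
  r2 <- pseudo_probabilities(iv, 0.7)
  r3 <- pseudo_probabilities(iv, 0.9)
  expect_true(all(r2$loci %in% r1$loci))
  expect_true(all(r3$loci %in% r2$loci))
  expect_lte(r1$L, sel$L)
  expect_true(all(r1$table$pseudo_p >= 0 & r1$table$pseudo_p <= 1))
  expect_error(pseudo_probabilities(iv, 0.4), "theta")
  expect_error(pseudo_probabilities(iv, 1), "theta")
})

test_that("pseudo-probability extremes map as expected", {
  iv <- structure(list(v = c(0.8, 0, -0.8) / sqrt(1.28), lambda = 1,
                       loci = 1:3, locus_id = c("a", "b", "c")),
                  class = "indicator_vector")
  r <- pseudo_probabilities(iv, 0.5)
  expect_equal(r$table$pseudo_p, c(1, 0.5, 0))
  expect_equal(r$table$symbol, c(2L, 1L, 1L))
  expect_equal(r$loci, c(1L, 3L))  # v' = 0 dropped at any theta > 0.5
  # raw diagnostics are on the RMS scale and may leave [0, 1]
  expect_true(any(r$table$pseudo_p_raw > 1 | r$table$pseudo_p_raw < 0))
})
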