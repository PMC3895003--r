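# Consistency and predictability procedures: phenotype-permutation overlap
# trials, random baselines, train/test splits, leave-two-out reduced
# classifiers, and subsample-size extrapolation.

# Fast modal classifier at threshold Lambda for given cohort row masks.
# Returns loci indices + word, computed straight from column counts.
.modal_at <- function(symbols, drows, crows, Lambda, side = "one") {
  n_d <- length(drows); n_c <- length(crows)
  x_d <- colSums(symbols[drows, , drop = FALSE] == 2L)
  x_c <- colSums(symbols[crows, , drop = FALSE] == 2L)
  p_d <- x_d / n_d; p_c <- x_c / n_c
  w <- odds(p_d) / odds(p_c)
  bnd <- x_d == 0L | x_d == n_d | x_c == 0L | x_c == n_c
  if (any(bnd))
    w[bnd] <- (haldane_odds(x_d, n_d) / haldane_odds(x_c, n_c))[bnd]
  keep <- if (side == "one") which(w >= Lambda)
          else which(pmax(w, 1 / w) >= Lambda)
  word <- ifelse(p_d[keep] >= 0.5, 2L, 1L)  # ties -> 2
  list(loci = keep, word = as.integer(word), omega = w[keep],
       p_d = p_d, p_c = p_c)
}

overlap_fraction <- function(ref, other) {
  if (!length(ref$loci)) return(NA_real_)
  idx <- match(ref$loci, other$loci)
  hit <- !is.na(idx) & other$word[idx] == ref$word
  sum(hit) / length(ref$loci)
}

rand_report <- function(mode, overlaps, n_trials, seed, L_ref) {
  structure(list(baseline_mode = mode, overlap_fractions = overlaps,
                 mean = mean(overlaps), sd = stats::sd(overlaps),
                 n_trials = n_trials, seed = seed, L_ref = L_ref),
            class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat("randomization_report (", x$baseline_mode, "): ", x$n_trials,
      " trials, L_ref = ", x$L_ref, "\n", sep = "")
  cat("  overlap fraction: mean", format(x$mean, digits = 4), " sd",
      format(x$sd, digits = 3), "\n")
  invisible(x)
}

#' Phenotype-permutation overlap trials
#'
#' Repeatedly permutes the case/control labels (cohort sizes fixed, the only
#' randomization that preserves every genotype statistic), recomputes the
#' modal classifier at the same threshold, and records the fraction of
#' reference classifier loci recovered with matching symbol. Under the
#' independence model of the three equiprobable binary alterations a
#' permuted classifier is expected to overlap the reference by 1/8.
#'
#' @param m a cleaned [allele_matrix()].
#' @param Lambda odds-ratio threshold of the reference classifier.
#' @param n_trials number of permutations (default 50).
#' @param seed integer seed.
#' @param side passed to the selection (`"one"` or `"two"`).
#' @return A `randomization_report`: per-trial overlap fractions, their
#'   mean and SD, the mode, and the reference classifier size.
#' @export
permutation_trials <- function(m, Lambda, n_trials = 50L, seed = 1L,
                               side = "one") {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  drows <- cohort_rows(m, "disease"); crows <- cohort_rows(m, "control")
  ref <- .modal_at(m$symbols, drows, crows, Lambda, side)
  n <- nrow(m$symbols); n_d <- length(drows)
  set.seed(seed)
  overlaps <- vapply(seq_len(n_trials), function(t) {
    perm <- sample.int(n)
    pd <- perm[seq_len(n_d)]; pc <- perm[-seq_len(n_d)]
    overlap_fraction(ref, .modal_at(m$symbols, pd, pc, Lambda, side))
  }, numeric(1))
  rand_report("permuted-labels", overlaps, n_trials, seed,
              length(ref$loci))
}

#' Simulate the three-alteration overlap model
#'
#' Independence model for how a randomized classifier can retain a
#' reference locus: three equiprobable binary alterations (symbol flip,
#' major-to-low drop, low-to-high entry), each preserving the locus with
#' probability 1/2, so a locus survives with probability 1/8. Provides the
#' analytic baseline that permutation trials are compared against.
#'
#' @param n_loci loci per trial.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return A `randomization_report` with per-trial survival fractions
#'   (expected mean 0.125).
#' @export
alteration_overlap_simulation <- function(n_loci, n_trials = 50L,
                                          seed = 1L) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  set.seed(seed)
  overlaps <- vapply(seq_len(n_trials), function(t) {
    keep <- matrix(stats::runif(3L * n_loci) < 0.5, nrow = 3L)
    mean(colSums(keep) == 3L)
  }, numeric(1))
  rand_report("alteration-model", overlaps, n_trials, seed, n_loci)
}

#' Random-locus baseline overlaps
#'
#' Draws `L_ref` loci uniformly without replacement from all 2M allele
#' loci and compares the resulting classifier with the reference. With
#' modal symbols the expected symbol-matched overlap is the hypergeometric
#' locus overlap L/(2M); with uniformly random symbols it is halved (when
#' cohort modes are equiprobable).
#'
#' @param m a cleaned [allele_matrix()].
#' @param Lambda threshold of the reference classifier.
#' @param mode `"random-loci-modal"` or `"random-loci-random-symbol"`.
#' @param n_trials,seed,side as in [permutation_trials()].
#' @return A `randomization_report`.
#' @export
random_baseline <- function(m, Lambda,
                            mode = c("random-loci-modal",
                                     "random-loci-random-symbol"),
                            n_trials = 50L, seed = 1L, side = "one") {
  mode <- match.arg(mode)
  if (n_trials < 1L) stop("n_trials must be >= 1")
  drows <- cohort_rows(m, "disease"); crows <- cohort_rows(m, "control")
  ref <- .modal_at(m$symbols, drows, crows, Lambda, side)
  L <- length(ref$loci); twoM <- ncol(m$symbols)
  if (L > twoM) stop("reference classifier larger than locus count")
  if (L == 0L) stop("empty reference classifier at Lambda = ", Lambda)
  # disease modal symbol at every locus, for the modal-symbol mode
  p_all <- colMeans(m$symbols[drows, , drop = FALSE] == 2L)
  mode_all <- ifelse(p_all >= 0.5, 2L, 1L)
  set.seed(seed)
  overlaps <- vapply(seq_len(n_trials), function(t) {
    loci <- sample.int(twoM, L)
    word <- if (mode == "random-loci-modal") mode_all[loci]
            else sample(c(1L, 2L), L, replace = TRUE)
    overlap_fraction(ref, list(loci = loci, word = word))
  }, numeric(1))
  rand_report(mode, overlaps, n_trials, seed, L)
}

#' Train/test split validation
#'
#' Splits both cohorts, computes the classifier (selection, modal word and
#' decision threshold) on the training set only, and reports train and test
#' error fractions at the training threshold. Selecting loci on the full
#' data (`select_on = "full"`) is allowed for diagnostics but triggers a
#' warning: once every sequence has influenced the locus selection the test
#' error no longer measures prediction.
#'
#' @param m a cleaned [allele_matrix()].
#' @param Lambda odds-ratio threshold.
#' @param train_fraction fraction of each cohort used for training
#'   (ignored when `train_sizes` is given).
#' @param train_sizes optional `c(n_cases, n_controls)` for the training
#'   set.
#' @param seed integer seed for the split.
#' @param side selection side.
#' @param select_on `"train"` (default) or `"full"`.
#' @return List with `L`, `Delta_star`, `train_error`, `test_error`,
#'   per-split confusion counts, and the split indices.
#' @export
split_validate <- function(m, Lambda, train_fraction = 0.85,
                           train_sizes = NULL, seed = 1L, side = "one",
                           select_on = c("train", "full")) {
  select_on <- match.arg(select_on)
  drows <- cohort_rows(m, "disease"); crows <- cohort_rows(m, "control")
  set.seed(seed)
  nt <- if (!is.null(train_sizes)) as.integer(train_sizes)
        else c(round(train_fraction * length(drows)),
               round(train_fraction * length(crows)))
  if (any(nt < 2L) || nt[1] >= length(drows) || nt[2] >= length(crows))
    stop("split leaves an empty or degenerate train/test cohort")
  tr_d <- sort(sample(drows, nt[1])); tr_c <- sort(sample(crows, nt[2]))
  te_d <- setdiff(drows, tr_d); te_c <- setdiff(crows, tr_c)
  if (select_on == "full") {
    warning("loci selected on the full data: test error is not a ",
            "measure of prediction")
    cls <- .modal_at(m$symbols, drows, crows, Lambda, side)
  } else {
    cls <- .modal_at(m$symbols, tr_d, tr_c, Lambda, side)
  }
  if (!length(cls$loci)) stop("empty selection at Lambda = ", Lambda)
  sc <- function(rows) {
    rowSums(m$symbols[rows, cls$loci, drop = FALSE] ==
              rep(cls$word, each = length(rows)))
  }
  s_trd <- sc(tr_d); s_trc <- sc(tr_c)
  fit <- fit_gaussians(s_trd, s_trc)
  roc <- roc_error(fit)
  err <- function(sd_, sc_) {
    fn <- sum(sd_ < roc$Delta_star); fp <- sum(sc_ >= roc$Delta_star)
    list(fn = fn, fp = fp,
         error_fraction = (fn + fp) / (length(sd_) + length(sc_)))
  }
  list(L = length(cls$loci), Lambda = Lambda,
       Delta_star = roc$Delta_star, E_min = roc$E_min,
       train = err(s_trd, s_trc), test = err(sc(te_d), sc(te_c)),
       train_error = err(s_trd, s_trc)$error_fraction,
       test_error = err(sc(te_d), sc(te_c))$error_fraction,
       split = list(train_disease = tr_d, train_control = tr_c,
                    test_disease = te_d, test_control = te_c))
}

#' Leave-two-out prediction with the bottom-ranked reduced classifier
#'
#' Per trial: one disease and one control sequence are removed at random
#' and held out; the modal classifier is recomputed on the rest; its loci
#' are ranked by the difference of the classifier-symbol frequency between
#' disease and control; only the bottom `n_bottom` loci are kept; both
#' held-out sequences are scored on that reduced classifier, and the trial
#' counts as correct when the disease sequence outscores the control one.
#' Reports the correct-prediction rate and an exact binomial sign-test
#' p-value against 0.5 (ties score as half).
#'
#' @param m a cleaned [allele_matrix()].
#' @param Lambda odds-ratio threshold.
#' @param n_bottom reduced classifier size.
#' @param n_trials number of leave-two-out trials (>= 1).
#' @param seed integer seed.
#' @param side selection side.
#' @return List with `rate`, `p_value`, `n_correct`, `n_ties`, `n_trials`,
#'   `mean_L`.
#' @export
reduced_classifier_prediction <- function(m, Lambda, n_bottom,
                                          n_trials = 1000L, seed = 1L,
                                          side = "one") {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  drows <- cohort_rows(m, "disease"); crows <- cohort_rows(m, "control")
  set.seed(seed)
  wins <- numeric(n_trials); Ls <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    hd <- sample(drows, 1L); hc <- sample(crows, 1L)
    cls <- .modal_at(m$symbols, setdiff(drows, hd), setdiff(crows, hc),
                     Lambda, side)
    if (n_bottom > length(cls$loci))
      stop("n_bottom (", n_bottom, ") exceeds classifier size (",
           length(cls$loci), ") in trial ", t)
    # frequency of the classifier symbol per cohort at classifier loci
    f_d <- ifelse(cls$word == 2L, cls$p_d[cls$loci],
                  1 - cls$p_d[cls$loci])
    f_c <- ifelse(cls$word == 2L, cls$p_c[cls$loci],
                  1 - cls$p_c[cls$loci])
    keep <- order(f_d - f_c)[seq_len(n_bottom)]
    loci <- cls$loci[keep]; word <- cls$word[keep]
    s_d <- sum(m$symbols[hd, loci] == word)
    s_c <- sum(m$symbols[hc, loci] == word)
    wins[t] <- if (s_d > s_c) 1 else if (s_d == s_c) 0.5 else 0
    Ls[t] <- length(cls$loci)
  }
  n_correct <- sum(wins == 1)
  bt <- stats::binom.test(n_correct, sum(wins != 0.5), p = 0.5,
                          alternative = "greater")
  list(rate = mean(wins), p_value = bt$p.value, n_correct = n_correct,
       n_ties = sum(wins == 0.5), n_trials = n_trials, mean_L = mean(Ls))
}

#' Subsample-size extrapolation of the selection size
#'
#' Repeatedly subsamples both cohorts at the given fractions, recomputes
#' the number of selected loci at the threshold, averages per fraction, and
#' fits L(n) = L_inf + beta / n (n the total subsample size) by least
#' squares. L_inf estimates the selection size in the limit of unbounded
#' data; the excess beta/n arises from finite-sample frequency noise.
#'
#' @param m a cleaned [allele_matrix()].
#' @param Lambda odds-ratio threshold.
#' @param fractions subsampling fractions in (0, 1\]; default
#'   `c(0.6, 0.7, 0.8, 0.9, 1)`.
#' @param n_repeats subsamples per fraction (default 5).
#' @param seed integer seed.
#' @param side selection side.
#' @return An object of class `subsample_curve`: list with `table`
#'   (`fraction`, `n`, `mean_L`, `sd_L`), `L_inf`, `beta`,
#'   `max_rel_residual`, `n_repeats`, `Lambda`, `seed`.
#' @export
subsample_extrapolation <- function(m, Lambda,
                                    fractions = c(0.6, 0.7, 0.8, 0.9, 1),
                                    n_repeats = 5L, seed = 1L,
                                    side = "one") {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  drows <- cohort_rows(m, "disease"); crows <- cohort_rows(m, "control")
  if (min(fractions) * min(length(drows), length(crows)) < 10)
    stop("smallest fraction leaves fewer than 10 samples in a cohort")
  set.seed(seed)
  tab <- lapply(fractions, function(f) {
    nd <- max(2L, round(f * length(drows)))
    nc <- max(2L, round(f * length(crows)))
    Ls <- vapply(seq_len(n_repeats), function(r) {
      sd_ <- if (nd == length(drows)) drows else sample(drows, nd)
      sc_ <- if (nc == length(crows)) crows else sample(crows, nc)
      length(.modal_at(m$symbols, sd_, sc_, Lambda, side)$loci)
    }, numeric(1))
    data.frame(fraction = f, n = nd + nc, mean_L = mean(Ls),
               sd_L = stats::sd(Ls))
  })
  tab <- do.call(rbind, tab)
  fit <- stats::lm(mean_L ~ I(1 / n), data = tab)
  L_inf <- unname(stats::coef(fit)[1]); beta <- unname(stats::coef(fit)[2])
  rel <- abs(stats::fitted(fit) - tab$mean_L) / pmax(tab$mean_L, 1)
  structure(list(table = tab, L_inf = L_inf, beta = beta,
                 max_rel_residual = max(rel), n_repeats = n_repeats,
                 Lambda = Lambda, seed = seed),
            class = "subsample_curve")
}

#' @export
print.subsample_curve <- function(x, ...) {
  cat("subsample_curve: L(n) = L_inf + beta/n fit at Lambda =", x$Lambda,
      "\n")
  cat("  L_inf =", format(x$L_inf, digits = 6), " beta =",
      format(x$beta, digits = 6), " max rel residual =",
      format(x$max_rel_residual, digits = 3), "\n")
  print(x$table)
  invisible(x)
}
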