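# High-value locus selection, the modal-word classifier, agreement scores,
# gaussian fits and the ROC error analysis.

#' Select high-value loci by allele odds-ratio threshold
#'
#' One-sided selection (the default) keeps allele loci whose odds ratio
#' omega is at least `Lambda`; the risk symbol at those loci is symbol 2
#' (enriched in disease). The two-sided option keeps loci with
#' max(omega, 1/omega) >= Lambda, the risk symbol being whichever symbol is
#' enriched in the disease cohort. Selections are nested: a larger Lambda
#' always selects a subset.
#'
#' @param stats a [locus_stats()] object (or a data.frame with `omega` and
#'   `locus_id` columns).
#' @param Lambda odds-ratio threshold; must exceed 1 for one-sided
#'   selection.
#' @param side `"one"` or `"two"`.
#' @return An object of class `locus_selection`: list with `Lambda`, `side`,
#'   `loci` (column indices into the allele matrix), `locus_id`, `omega`,
#'   `risk_symbol`, and `L` (the selection size).
#' @export
select_high_value <- function(stats, Lambda, side = c("one", "two")) {
  side <- match.arg(side)
  allele <- if (inherits(stats, "locus_stats")) stats$allele else stats
  if (side == "one" && Lambda <= 1)
    stop("one-sided selection requires Lambda > 1")
  omega <- allele$omega
  if (side == "one") {
    keep <- which(omega >= Lambda)
    risk <- rep(2L, length(keep))
  } else {
    keep <- which(pmax(omega, 1 / omega) >= Lambda)
    risk <- ifelse(omega[keep] >= 1, 2L, 1L)
  }
  structure(list(Lambda = Lambda, side = side, loci = keep,
                 locus_id = allele$locus_id[keep], omega = omega[keep],
                 risk_symbol = risk, L = length(keep)),
            class = "locus_selection")
}

#' @export
print.locus_selection <- function(x, ...) {
  cat("locus_selection: L =", x$L, "allele loci at Lambda =", x$Lambda,
      paste0("(", x$side, "-sided)\n"))
  invisible(x)
}

#' Modal-word classifier over a locus selection
#'
#' The mode word takes, at each selected allele locus, the modal (most
#' frequent) symbol of the disease cohort; an exact 50/50 tie takes `tie`
#' (default symbol 2).
#'
#' @param m a cleaned [allele_matrix()].
#' @param selection a [select_high_value()] result.
#' @param tie tie-break symbol, default `2L`.
#' @return An object of class `modal_indicator`: list with `selection`,
#'   `loci`, `locus_id`, `word` (integer symbols in \{1, 2\}), `L`.
#' @export
mode_word <- function(m, selection, tie = 2L) {
  rows <- cohort_rows(m, "disease")
  if (!length(rows)) stop("empty disease cohort")
  p <- colMeans(m$symbols[rows, selection$loci, drop = FALSE] == 2L)
  word <- ifelse(p > 0.5, 2L, ifelse(p < 0.5, 1L, as.integer(tie)))
  structure(list(selection = selection, loci = selection$loci,
                 locus_id = selection$locus_id, word = as.integer(word),
                 L = selection$L),
            class = "modal_indicator")
}

#' Agreement score of sequences against a classifier word
#'
#' The score of a sample is the number of selected loci at which its symbol
#' agrees with the classifier word; equivalently L minus the Hamming
#' distance between the projected sequence and the word. `score_sequences()`
#' scores every sample of the matrix; `score_sequence()` scores one symbol
#' vector (full-length or already projected onto the selection).
#'
#' @param m an [allele_matrix()] with no missing entries at selected loci.
#' @param classifier a `modal_indicator` or `refined_classifier` (anything
#'   with `loci` and `word`).
#' @return `score_sequences()`: `data.frame` with `sample_id`, `label`,
#'   `score`. `score_sequence()`: a single integer.
#' @export
score_sequences <- function(m, classifier) {
  sub <- m$symbols[, classifier$loci, drop = FALSE]
  if (anyNA(sub)) stop("missing symbols at selected loci; impute first")
  sc <- as.integer(rowSums(sub == rep(classifier$word, each = nrow(sub))))
  data.frame(sample_id = m$sample_ids, label = as.character(m$labels),
             score = sc, stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname score_sequences
#' @param sequence integer symbol vector; either of length 2M (indexed by
#'   `classifier$loci`) or already of length L.
#' @export
score_sequence <- function(sequence, classifier) {
  proj <- if (length(sequence) == length(classifier$word)) sequence
          else sequence[classifier$loci]
  if (anyNA(proj)) stop("missing symbol at a selected locus")
  sum(proj == classifier$word)
}

#' Gaussian fits to the two cohorts' score distributions
#'
#' Scores are sums over many loci, so by the central limit theorem each
#' cohort's score distribution is summarized by a normal fit: sample mean
#' and unbiased standard deviation. A degenerate (constant-score) cohort is
#' flagged, not fatal.
#'
#' @param scores_d,scores_c numeric score vectors for the disease and
#'   control cohorts (each of length >= 2).
#' @return List with `mu_d`, `sigma_d`, `mu_c`, `sigma_c`, `n_d`, `n_c`,
#'   `degenerate` (logical, per cohort).
#' @export
fit_gaussians <- function(scores_d, scores_c) {
  if (length(scores_d) < 2L || length(scores_c) < 2L)
    stop("need at least 2 samples per cohort")
  fit <- list(mu_d = mean(scores_d), sigma_d = stats::sd(scores_d),
              mu_c = mean(scores_c), sigma_c = stats::sd(scores_c),
              n_d = length(scores_d), n_c = length(scores_c))
  fit$degenerate <- c(disease = fit$sigma_d == 0, control = fit$sigma_c == 0)
  if (any(fit$degenerate))
    warning("degenerate score distribution (sigma = 0) in: ",
            paste(names(fit$degenerate)[fit$degenerate], collapse = ", "))
  fit
}

#' ROC error analysis of the gaussian score model
#'
#' Under the gaussian fits, T(Delta) is the fraction of the disease cohort
#' with score >= Delta and FP(Delta) the corresponding control fraction.
#' The error fraction E(Delta) = \[n_d (1 - T) + n_c FP\] / (n_d + n_c) is
#' minimized over a fine grid spanning both means +/- 4 standard
#' deviations; the minimizing threshold Delta* defines the decision rule
#' "score >= Delta* is disease". When raw scores are supplied the empirical
#' misclassification counts at Delta* are also reported.
#'
#' @param fit a [fit_gaussians()] result.
#' @param n_d,n_c cohort sizes (default taken from `fit`).
#' @param grid_points grid resolution (default 1e4).
#' @param scores optional `data.frame` from [score_sequences()] for the
#'   empirical-count version.
#' @return An object of class `score_model`: list with `roc` (`Delta`,
#'   `TPR`, `FPR`, `E`), `Delta_star`, `E_min`, expected false
#'   negative/positive counts at Delta*, the `fit`, and (if scores given)
#'   `empirical` counts and error fraction at Delta*.
#' @export
roc_error <- function(fit, n_d = fit$n_d, n_c = fit$n_c,
                      grid_points = 1e4L, scores = NULL) {
  s_d <- max(fit$sigma_d, .Machine$double.eps)
  s_c <- max(fit$sigma_c, .Machine$double.eps)
  lo <- min(fit$mu_d, fit$mu_c) - 4 * max(s_d, s_c)
  hi <- max(fit$mu_d, fit$mu_c) + 4 * max(s_d, s_c)
  Delta <- seq(lo, hi, length.out = grid_points)
  TPR <- stats::pnorm(Delta, fit$mu_d, s_d, lower.tail = FALSE)
  FPR <- stats::pnorm(Delta, fit$mu_c, s_c, lower.tail = FALSE)
  E <- (n_d * (1 - TPR) + n_c * FPR) / (n_d + n_c)
  i <- which.min(E)
  out <- list(roc = data.frame(Delta = Delta, TPR = TPR, FPR = FPR, E = E),
              Delta_star = Delta[i], E_min = E[i],
              expected_fn = n_d * (1 - TPR[i]), expected_fp = n_c * FPR[i],
              fit = fit)
  if (!is.null(scores)) {
    d <- scores$score[scores$label == "disease"]
    c_ <- scores$score[scores$label == "control"]
    fn <- sum(d < out$Delta_star)
    fp <- sum(c_ >= out$Delta_star)
    out$empirical <- list(fn = fn, fp = fp,
                          error_fraction = (fn + fp) / (length(d) + length(c_)))
  }
  class(out) <- "score_model"
  out
}

#' @export
print.score_model <- function(x, ...) {
  cat("score_model: Delta* =", format(x$Delta_star, digits = 6),
      " E_min =", format(x$E_min, digits = 4), "\n")
  cat("  gaussian fits: disease N(", format(x$fit$mu_d, digits = 6), ",",
      format(x$fit$sigma_d, digits = 4), ")  control N(",
      format(x$fit$mu_c, digits = 6), ",",
      format(x$fit$sigma_c, digits = 4), ")\n")
  if (!is.null(x$empirical))
    cat("  empirical at Delta*:", x$empirical$fn, "FN +", x$empirical$fp,
        "FP ( error fraction", format(x$empirical$error_fraction,
                                      digits = 4), ")\n")
  invisible(x)
}

#' Classify scores at a decision threshold
#' @param scores numeric scores or a [score_sequences()] data.frame.
#' @param Delta_star decision threshold; score >= Delta_star is disease.
#' @return Character vector of predicted labels.
#' @export
classify_scores <- function(scores, Delta_star) {
  s <- if (is.data.frame(scores)) scores$score else scores
  ifelse(s >= Delta_star, "disease", "control")
}

#' Locate plateaus ("sweet spots") of the threshold-set-size curve
#'
#' Scans N(Lambda) for windows of width `width` over which the relative
#' change in N is below `tol`; such plateaus mark thresholds where the
#' selection is insensitive to the exact cutoff.
#'
#' @param hist an [odds_histograms()] result (its `N_of_Lambda` is used) or
#'   a data.frame with `Lambda` and `N`.
#' @param tol relative-change tolerance (default 0.01).
#' @param width Lambda window width (default 0.1).
#' @return `data.frame` of plateau windows: `Lambda_lo`, `Lambda_hi`,
#'   `N_lo`, `N_hi`, `rel_change`.
#' @export
sweet_spot <- function(hist, tol = 0.01, width = 0.1) {
  tab <- if (inherits(hist, "odds_histogram")) hist$N_of_Lambda else hist
  out <- data.frame(Lambda_lo = numeric(), Lambda_hi = numeric(),
                    N_lo = numeric(), N_hi = numeric(),
                    rel_change = numeric())
  for (i in seq_len(nrow(tab))) {
    j <- which(tab$Lambda >= tab$Lambda[i] + width)
    if (!length(j)) break
    j <- j[1]
    if (tab$N[i] == 0) next
    rel <- (tab$N[i] - tab$N[j]) / tab$N[i]
    if (rel < tol)
      out[nrow(out) + 1L, ] <- c(tab$Lambda[i], tab$Lambda[j],
                                 tab$N[i], tab$N[j], rel)
  }
  out
}

#' Score-model parameters across a grid of thresholds
#'
#' Tabulates L, the gaussian fit parameters and the ROC summary as the
#' odds-ratio threshold varies, so scalings of (mu, sigma, L) with Lambda
#' can be inspected or fit by the user. Nothing is asserted about the form
#' of those scalings.
#'
#' @param m a cleaned [allele_matrix()].
#' @param stats a [locus_stats()] object for `m`.
#' @param Lambdas numeric vector of thresholds (> 1).
#' @return `data.frame` with one row per Lambda: `Lambda`, `L`, `mu_d`,
#'   `sigma_d`, `mu_c`, `sigma_c`, `Delta_star`, `E_min`.
#' @export
score_scaling_table <- function(m, stats, Lambdas) {
  rows <- lapply(Lambdas, function(l) {
    sel <- select_high_value(stats, l)
    if (sel$L == 0L)
      return(data.frame(Lambda = l, L = 0L, mu_d = NA, sigma_d = NA,
                        mu_c = NA, sigma_c = NA, Delta_star = NA,
                        E_min = NA))
    w <- mode_word(m, sel)
    sc <- score_sequences(m, w)
    fit <- fit_gaussians(sc$score[sc$label == "disease"],
                         sc$score[sc$label == "control"])
    roc <- roc_error(fit)
    data.frame(Lambda = l, L = sel$L, mu_d = fit$mu_d,
               sigma_d = fit$sigma_d, mu_c = fit$mu_c,
               sigma_c = fit$sigma_c, Delta_star = roc$Delta_star,
               E_min = roc$E_min)
  })
  do.call(rbind, rows)
}
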