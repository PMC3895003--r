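# Euclidean embedding of standard-form sequences, the criterion-functional
# eigenproblem solved by the method of snapshots, and the pseudo-probability
# refinement of the classifier.

#' Ratio of squared Euclidean to Hamming distance under the default
#' embedding (\{1 -> -1, 2 -> +1\}): D_E^2 = 4 D_H.
#' @export
EMBED_HAMMING_FACTOR <- 4

#' Embed standard-form sequences in Euclidean space
#'
#' Maps symbol 2 to +1 and symbol 1 to -1, restricted to the selected loci,
#' so the squared Euclidean distance between two embedded sequences equals
#' [EMBED_HAMMING_FACTOR] times their Hamming distance, and the cohort mean
#' at a locus with symbol-2 probability p is 2p - 1.
#'
#' @param m a cleaned [allele_matrix()].
#' @param selection optional [select_high_value()] result; `NULL` embeds all
#'   loci.
#' @return An object of class `embedded_cohort`: list with `D` (n_d x L
#'   disease matrix), `C` (n_c x L control matrix), `selection`, `loci`,
#'   `locus_id`, and per-cohort `sample_ids`.
#' @export
embed_cohorts <- function(m, selection = NULL) {
  loci <- if (is.null(selection)) seq_len(ncol(m$symbols)) else selection$loci
  sub <- m$symbols[, loci, drop = FALSE]
  if (anyNA(sub)) stop("missing symbols; impute before embedding")
  X <- 2 * sub - 3  # 1 -> -1, 2 -> +1
  drow <- cohort_rows(m, "disease"); crow <- cohort_rows(m, "control")
  structure(list(D = X[drow, , drop = FALSE], C = X[crow, , drop = FALSE],
                 selection = selection, loci = loci,
                 locus_id = colnames(m$symbols)[loci],
                 sample_ids = list(disease = m$sample_ids[drow],
                                   control = m$sample_ids[crow])),
            class = "embedded_cohort")
}

#' Criterion value of a direction
#'
#' Mean squared projection of the disease rows minus that of the control
#' rows, for a unit vector `v`: the quantity the indicator vector
#' maximizes.
#'
#' @param E an [embed_cohorts()] result.
#' @param v numeric vector of length L (normalized internally).
#' @return Scalar criterion value.
#' @export
criterion_value <- function(E, v) {
  v <- v / sqrt(sum(v^2))
  mean((E$D %*% v)^2) - mean((E$C %*% v)^2)
}

#' Solve for the indicator vector
#'
#' Finds the unit vector v maximizing the disease-minus-control
#' mean-squared-projection contrast, i.e. the leading eigenvector of
#' K = D'D/n_d - C'C/n_c. For L >> n the eigenproblem is solved in snapshot
#' space: with X the stacked data and W = diag(+1/n_d on disease rows,
#' -1/n_c on control rows), the n x n problem W X X' a = lambda a is solved
#' and v = X'a (normalized) — the method of snapshots. The sign is fixed so
#' that v has non-negative inner product with mean(D) - mean(C). A warning
#' (not an error) fires if no positive eigenvalue exists.
#'
#' @param E an [embed_cohorts()] result with >= 2 samples per cohort.
#' @param method `"auto"` (snapshot when L > n, direct otherwise),
#'   `"snapshot"`, or `"direct"`.
#' @return An object of class `indicator_vector`: list with `v` (unit
#'   vector), `lambda` (leading eigenvalue = criterion value),
#'   `snapshot_coeffs` (a, or `NULL` for the direct path), `method`,
#'   `residual`, plus the `selection`/`loci`/`locus_id` carried from `E`.
#' @export
solve_indicator <- function(E, method = c("auto", "snapshot", "direct")) {
  method <- match.arg(method)
  n_d <- nrow(E$D); n_c <- nrow(E$C)
  if (n_d < 2L || n_c < 2L) stop("need at least 2 samples per cohort")
  L <- ncol(E$D)
  if (all(E$D == 0) && all(E$C == 0)) stop("all-zero data")
  if (method == "auto") method <- if (L > n_d + n_c) "snapshot" else "direct"
  a <- NULL; residual <- NA_real_
  if (method == "snapshot") {
    X <- rbind(E$D, E$C)
    w <- c(rep(1 / n_d, n_d), rep(-1 / n_c, n_c))
    G <- tcrossprod(X)          # n x n Gram matrix X X'
    WG <- w * G                 # diag(w) %*% G, nonsymmetric
    eg <- eigen(WG)
    lam <- Re(eg$values)
    # keep only numerically real eigenpairs
    real_ok <- abs(Im(eg$values)) <= 1e-8 * (abs(lam) + 1e-12)
    lam[!real_ok] <- -Inf
    i <- which.max(lam)
    lambda <- lam[i]
    a <- Re(eg$vectors[, i])
    residual <- sqrt(sum((WG %*% a - lambda * a)^2)) / sqrt(sum(a^2))
    if (residual > 1e-8)
      warning("snapshot eigenpair residual ", format(residual),
              " exceeds 1e-8")
    v <- as.vector(crossprod(X, a))
  } else {
    K <- crossprod(E$D) / n_d - crossprod(E$C) / n_c
    eg <- eigen(K, symmetric = TRUE)
    lambda <- eg$values[1L]
    v <- eg$vectors[, 1L]
  }
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate eigenvector (zero norm)")
  v <- v / nv
  dir <- colMeans(E$D) - colMeans(E$C)
  if (sum(v * dir) < 0) { v <- -v; if (!is.null(a)) a <- -a }
  if (lambda <= 0)
    warning("no positive eigenvalue: cohorts are not separable ",
            "along any direction (leading lambda = ", format(lambda), ")")
  structure(list(v = v, lambda = lambda, snapshot_coeffs = a,
                 method = method, residual = residual,
                 selection = E$selection, loci = E$loci,
                 locus_id = E$locus_id),
            class = "indicator_vector")
}

#' @export
print.indicator_vector <- function(x, ...) {
  cat("indicator_vector: L =", length(x$v), " lambda =",
      format(x$lambda, digits = 6), paste0("(", x$method, " path)\n"))
  invisible(x)
}

#' Pseudo-probability refinement of the indicator vector
#'
#' Rescales the indicator vector by its largest absolute component,
#' v' = v / max|v|, and maps each component to a pseudo-probability for
#' symbol 2, p* = (1 + v') / 2. Loci are retained when
#' max(p*, 1 - p*) > theta ("overprobable" loci); the refined classifier
#' word takes symbol 2 where v' > 0 and symbol 1 otherwise. A diagnostic
#' unnormalized pseudo-probability, computed on the root-mean-square
#' component scale (v / sqrt(1/L)), is also reported; unlike p* it can
#' leave \[0, 1\] in either direction.
#'
#' @param iv a [solve_indicator()] result.
#' @param theta retention level in \[0.5, 1); default 0.5.
#' @return An object of class `refined_classifier`: list with `table`
#'   (per-locus `locus_id`, `v`, `v_scaled`, `pseudo_p`, `pseudo_p_raw`,
#'   `retained`, `symbol`), `loci` and `word` (retained loci only, usable
#'   with [score_sequences()]), `theta`, `L`.
#' @export
pseudo_probabilities <- function(iv, theta = 0.5) {
  if (theta < 0.5 || theta >= 1) stop("theta must lie in [0.5, 1)")
  v <- iv$v
  vmax <- max(abs(v))
  if (vmax == 0) stop("zero indicator vector")
  vs <- v / vmax
  p <- (1 + vs) / 2
  p_raw <- (1 + v / sqrt(1 / length(v))) / 2
  retained <- pmax(p, 1 - p) > theta
  symbol <- ifelse(vs > 0, 2L, 1L)
  tab <- data.frame(locus_id = iv$locus_id, v = v, v_scaled = vs,
                    pseudo_p = p, pseudo_p_raw = p_raw,
                    retained = retained, symbol = symbol,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, loci = iv$loci[retained],
                 locus_id = iv$locus_id[retained],
                 word = symbol[retained], theta = theta,
                 L = sum(retained), lambda = iv$lambda),
            class = "refined_classifier")
}

#' @export
print.refined_classifier <- function(x, ...) {
  cat("refined_classifier:", x$L, "of", nrow(x$table),
      "loci retained at theta =", x$theta, "\n")
  invisible(x)
}
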