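# Intra-cohort Hamming structure matrices, mean-distance reordering, and
# reordered score traces.

#' Intra-cohort Hamming structure matrix
#'
#' Pairwise Hamming distances between a cohort's sequences on the selected
#' loci, plus the histogram of the upper-triangle distances with its
#' gaussian fit (mean, SD). The squared Euclidean distances of the embedded
#' cohort equal [EMBED_HAMMING_FACTOR] times these entries.
#'
#' @param m a cleaned [allele_matrix()].
#' @param selection optional [select_high_value()] result; `NULL` uses all
#'   loci.
#' @param cohort `"disease"` or `"control"`.
#' @param bins histogram bin count (default 100).
#' @return An object of class `structure_matrix`: list with `distances`
#'   (n x n integer matrix), `ordering` (permutation of 1..n; identity until
#'   [reorder_by_mean_distance()] is applied), `cohort`, `sample_ids`, `L`,
#'   `histogram` (`mid`, `count`, `density`), `fit` (`mean`, `sd`).
#' @export
hamming_matrix <- function(m, selection = NULL, cohort = c("disease",
                                                           "control"),
                           bins = 100L) {
  cohort <- match.arg(cohort)
  rows <- cohort_rows(m, cohort)
  if (!length(rows)) stop("empty cohort: ", cohort)
  loci <- if (is.null(selection)) seq_len(ncol(m$symbols)) else selection$loci
  sub <- m$symbols[rows, loci, drop = FALSE]
  if (anyNA(sub)) stop("missing symbols; impute first")
  # symbols are 1/2, so manhattan distance counts disagreements exactly
  d <- as.matrix(stats::dist(sub, method = "manhattan"))
  storage.mode(d) <- "integer"
  dimnames(d) <- list(m$sample_ids[rows], m$sample_ids[rows])
  up <- d[upper.tri(d)]
  h <- graphics::hist(up, breaks = bins, plot = FALSE)
  structure(list(distances = d, ordering = seq_along(rows),
                 cohort = cohort, sample_ids = m$sample_ids[rows],
                 L = length(loci),
                 histogram = data.frame(mid = h$mids, count = h$counts,
                                        density = h$density),
                 fit = c(mean = mean(up), sd = stats::sd(up))),
            class = "structure_matrix")
}

#' @export
print.structure_matrix <- function(x, ...) {
  cat("structure_matrix (", x$cohort, "): ", nrow(x$distances), " x ",
      ncol(x$distances), " on L = ", x$L, " loci\n", sep = "")
  cat("  distance histogram fit: mean", format(x$fit["mean"], digits = 5),
      " sd", format(x$fit["sd"], digits = 4), "\n")
  invisible(x)
}

mean_offdiag <- function(d) {
  n <- nrow(d)
  (rowSums(d) - diag(d)) / (n - 1L)
}

#' Reorder a structure matrix by ascending mean Hamming distance
#'
#' Rows and columns are permuted so that sequences appear in ascending
#' order of their mean Hamming distance to all others (self excluded);
#' ties keep their current relative order, which makes the operation
#' idempotent. `ordering` accumulates the permutation relative to the
#' original sample order.
#'
#' @param s a [hamming_matrix()] result.
#' @return The reordered `structure_matrix`.
#' @export
reorder_by_mean_distance <- function(s) {
  md <- mean_offdiag(s$distances)
  perm <- order(md, seq_along(md))
  s$distances <- s$distances[perm, perm, drop = FALSE]
  s$ordering <- s$ordering[perm]
  s$sample_ids <- s$sample_ids[perm]
  s
}

#' Scores in structure-matrix order
#'
#' Lists per-sample scores in the ordering of a (reordered) structure
#' matrix, the trace plotted against rank. Points are excluded from the
#' trace only on explicit request (`exclude`, original sample indices);
#' nothing is dropped automatically.
#'
#' @param scores numeric scores in the cohort's original sample order.
#' @param ordering integer permutation (the `ordering` element of a
#'   `structure_matrix`).
#' @param exclude integer indices (in the original order) to omit.
#' @return `data.frame` with `rank`, `original_index`, `score`.
#' @export
reordered_scores <- function(scores, ordering, exclude = integer(0)) {
  if (length(scores) != length(ordering))
    stop("scores and ordering lengths differ (", length(scores), " vs ",
         length(ordering), ")")
  keep <- !(ordering %in% exclude)
  data.frame(rank = seq_len(sum(keep)),
             original_index = ordering[keep],
             score = scores[ordering][keep], row.names = NULL)
}

#' Write a structure matrix as a grayscale PGM heatmap
#'
#' Minimal plain-text (P2) PGM rendering of the distance matrix, darkest at
#' the largest distance.
#'
#' @param s a `structure_matrix`.
#' @param path output path.
#' @param levels gray levels (default 255).
#' @return `path`, invisibly.
#' @export
write_structure_pgm <- function(s, path, levels = 255L) {
  d <- s$distances
  rng <- range(d)
  g <- if (rng[2] > rng[1])
    round(levels * (1 - (d - rng[1]) / (rng[2] - rng[1]))) else
    matrix(levels, nrow(d), ncol(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), as.character(levels)), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
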