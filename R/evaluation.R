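#' Mean average error of inferred clone proportions
#'
#' For each spot, the mean over clones of the absolute difference between
#' inferred and true proportions; averaged over spots. Bounded by
#' `2 * (K - 1) / K` (total-variation style bound on simplex rows).
#'
#' @param H_true,H_est S x K proportion matrices with rows on the simplex.
#' @return Scalar MAE.
#' @export
mean_average_error <- function(H_true, H_est) {
  H_true <- as.matrix(H_true); H_est <- as.matrix(H_est)
  if (!identical(dim(H_true), dim(H_est)))
    stop("H_true and H_est must have identical dimensions")
  mean(rowMeans(abs(H_est - H_true)))
}

#' Major-clone accuracy
#'
#' Fraction of spots whose predicted predominant clone (argmax proportion)
#' matches the true predominant clone. Ties resolve to the lowest clone
#' index on both sides, deterministically.
#'
#' @inheritParams mean_average_error
#' @return Fraction in \[0, 1\].
#' @export
major_clone_accuracy <- function(H_true, H_est) {
  H_true <- as.matrix(H_true); H_est <- as.matrix(H_est)
  if (!identical(dim(H_true), dim(H_est)))
    stop("H_true and H_est must have identical dimensions")
  mean(max.col(H_est, ties.method = "first") ==
         max.col(H_true, ties.method = "first"))
}

#' Major clone per spot
#'
#' @param H S x K proportion matrix.
#' @return Integer vector of argmax clone indices (ties to lowest index).
#' @export
major_clone <- function(H) max.col(as.matrix(H), ties.method = "first")

#' Sample adjacent or distant spot pairs
#'
#' Adjacent pairs satisfy `|dx| <= 1` and `|dy| <= 1` on the array grid;
#' distant pairs satisfy `|dx| > 1` and `|dy| > 1`. Pairs are drawn
#' uniformly without replacement from all qualifying unordered pairs.
#'
#' @param coords S x 2 grid coordinates.
#' @param n_pairs number of pairs to draw.
#' @param mode `"adjacent"` or `"distant"`.
#' @return Object of class `spot_pair_set`: list with integer matrix
#'   `pairs` (n_pairs x 2 spot indices) and `mode`.
#' @export
sample_spot_pairs <- function(coords, n_pairs, mode = c("adjacent", "distant")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  S <- nrow(coords)
  idx <- which(upper.tri(matrix(TRUE, S, S)), arr.ind = TRUE)
  dx <- abs(coords[idx[, 1], 1] - coords[idx[, 2], 1])
  dy <- abs(coords[idx[, 1], 2] - coords[idx[, 2], 2])
  ok <- if (mode == "adjacent") dx <= 1 & dy <= 1 else dx > 1 & dy > 1
  qual <- idx[ok, , drop = FALSE]
  if (nrow(qual) < n_pairs)
    stop("only ", nrow(qual), " qualifying ", mode, " pairs exist; ",
         n_pairs, " requested")
  take <- sample.int(nrow(qual), n_pairs)
  structure(list(pairs = unname(qual[take, , drop = FALSE]), mode = mode),
            class = "spot_pair_set")
}

#' Per-clone correlation of proportions across spot pairs
#'
#' For each clone, the Pearson correlation between the proportions in the
#' first and the second member of each pair. Clones with zero variance on
#' either side are reported as `NA`.
#'
#' @param H S x K proportion matrix.
#' @param pairs a [sample_spot_pairs()] result.
#' @return Numeric vector of K correlations (possibly `NA`).
#' @export
pair_clonal_correlation <- function(H, pairs) {
  H <- as.matrix(H)
  pm <- pairs$pairs
  if (nrow(pm) < 3) stop("need at least 3 pairs")
  vapply(seq_len(ncol(H)), function(k) {
    a <- H[pm[, 1], k]; b <- H[pm[, 2], k]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
}

#' Major-clone agreement across spot pairs
#'
#' @param assignments length-S vector of clone indices (one clone per
#'   spot, e.g. from [major_clone()]).
#' @param pairs a [sample_spot_pairs()] result.
#' @return Fraction of pairs whose two spots carry the same clone.
#' @export
pair_major_clone_agreement <- function(assignments, pairs) {
  pm <- pairs$pairs
  if (nrow(pm) < 1) stop("empty pair set")
  mean(assignments[pm[, 1]] == assignments[pm[, 2]])
}

#' Compare adjacent against distant spot-pair statistics
#'
#' One-sided Wilcoxon rank-sum test of the alternative that the adjacent
#' values are stochastically larger than the distant ones, with both
#' medians reported.
#'
#' @param values_adj,values_dist non-empty numeric vectors (e.g. pooled
#'   pair correlations).
#' @return List with `median_adj`, `median_dist`, `p_value`.
#' @export
compare_adjacent_vs_distant <- function(values_adj, values_dist) {
  values_adj <- values_adj[is.finite(values_adj)]
  values_dist <- values_dist[is.finite(values_dist)]
  if (length(values_adj) == 0 || length(values_dist) == 0)
    stop("both input vectors must be non-empty")
  p <- suppressWarnings(
    wilcox.test(values_adj, values_dist, alternative = "greater")$p.value)
  list(median_adj = median(values_adj), median_dist = median(values_dist),
       p_value = p)
}
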