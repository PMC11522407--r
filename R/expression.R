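#' Cell-count-weighted design matrix
#'
#' Row `s` is `N_s * H_s,.`: the expected number of cells of each clone in
#' spot `s`. Row sums equal the cell counts because proportion rows lie on
#' the simplex.
#'
#' @param H S x K clone-proportion matrix (rows on the simplex).
#' @param N length-S cell counts, all `>= 1`.
#' @return S x K numeric matrix.
#' @export
build_design_matrix <- function(H, N) {
  H <- as.matrix(H)
  if (length(N) != nrow(H)) stop("N must have one entry per row of H")
  if (any(N < 1)) stop("cell counts must be >= 1")
  sweep(H, 1, as.numeric(N), "*")
}

#' Deconvolve clone-specific expression profiles
#'
#' Solves, independently for every gene `g`, the non-negative
#' least-squares problem
#' \deqn{\min_{b \ge 0} \| N' H b - Y_{.,g} \|_2}
#' with no intercept, where `N'` is the diagonal matrix of cell counts.
#' The solution `B[k, g]` is the average expression of gene `g` in one
#' cell of clone `k`. With a rank-deficient design a solution is still
#' returned and flagged via the `"nonunique"` attribute.
#'
#' @param H S x K inferred clone proportions.
#' @param N length-S cell counts.
#' @param Y S x G spot-by-gene expression counts, non-negative.
#' @param normalize optionally divide each spot row of `Y` by its total
#'   and rescale to the mean depth before regression; off by default (raw
#'   counts are regressed).
#' @return K x G non-negative matrix `B`, gene names preserved; attribute
#'   `nonunique` is `TRUE` when the design is rank-deficient.
#' @export
deconvolve_clone_expression <- function(H, N, Y, normalize = FALSE) {
  H <- as.matrix(H); Y <- as.matrix(Y)
  if (nrow(Y) != nrow(H)) stop("Y must have one row per spot")
  if (any(Y < 0)) stop("expression counts must be non-negative")
  if (isTRUE(normalize)) {
    depth <- rowSums(Y)
    depth[depth == 0] <- 1
    Y <- Y / depth * mean(depth)
  }
  X <- build_design_matrix(H, N)
  K <- ncol(H); G <- ncol(Y)
  B <- matrix(0, K, G)
  for (g in seq_len(G)) B[, g] <- pracma::lsqnonneg(X, Y[, g])$x
  rownames(B) <- colnames(H)
  colnames(B) <- colnames(Y)
  attr(B, "nonunique") <- qr(X)$rank < K
  B
}

#' Rank genes by their maximum clone-level expression
#'
#' Genes are ordered by decreasing maximum of `B` over clones; ties break
#' lexicographically by gene label.
#'
#' @param B K x G clone-expression matrix with gene column names.
#' @param top_n number of genes to return, `<= G`.
#' @return Character vector of `top_n` gene names, most active first.
#' @export
rank_genes_by_clone_expression <- function(B, top_n = ncol(B)) {
  B <- as.matrix(B)
  if (top_n > ncol(B)) stop("top_n exceeds the number of genes")
  genes <- colnames(B) %||% paste0("gene", seq_len(ncol(B)))
  mx <- apply(B, 2, max)
  genes[order(-mx, genes)][seq_len(top_n)]
}
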