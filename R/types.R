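#' Clone genotypes and prevalences
#'
#' Container for the clonal structure reconstructed upstream from bulk
#' DNA-seq: a genotype matrix of zygosity values and the prevalence of each
#' clone in the bulk sample. Prevalences are discretized into 20 bins and
#' rescaled (see [discretize_prevalence()]); the discretized values act as
#' Dirichlet/Gamma shape parameters for clones present in a spot, while
#' absent clones receive the small pseudo-frequency `F0` so that all
#' proportions stay strictly positive.
#'
#' @param C numeric matrix, M mutations x K clones, zygosity values in
#'   \[0, 1\] (fraction of alleles carrying the mutation in that clone).
#' @param F_prev numeric vector of K clone prevalences, non-negative and
#'   summing to 1 (tolerance 1e-8).
#' @param F0 pseudo-frequency given to clones marked absent from a spot;
#'   must be positive. Default 0.01.
#' @param l multiplicative scaling factor applied to the discretized
#'   prevalences. Default 100.
#' @return An object of class `clone_set` with elements `C`, `F`, `F_disc`,
#'   `F0`, `l`, `M`, `K`.
#' @export
clone_set <- function(C, F_prev, F0 = 0.01, l = 100) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (any(!is.finite(C)) || any(C < 0) || any(C > 1))
    stop("genotype matrix C must have entries in [0, 1]")
  K <- ncol(C)
  if (length(F_prev) != K)
    stop("length of F_prev (", length(F_prev), ") must equal ncol(C) (", K, ")")
  if (any(F_prev < 0)) stop("clone prevalences must be non-negative")
  if (abs(sum(F_prev) - 1) > 1e-8)
    stop("clone prevalences must sum to 1 (got ", format(sum(F_prev)), ")")
  if (F0 <= 0) stop("F0 must be positive")
  if (l <= 0) stop("l must be positive")
  if (is.null(colnames(C))) colnames(C) <- paste0("clone", seq_len(K))
  if (is.null(rownames(C))) rownames(C) <- paste0("mut", seq_len(nrow(C)))
  structure(
    list(C = C, F = as.numeric(F_prev),
         F_disc = discretize_prevalence(F_prev, l),
         F0 = F0, l = l, M = nrow(C), K = K),
    class = "clone_set")
}

#' Per-spot read counts, coordinates and cell-count priors
#'
#' @param A integer matrix, M x S, alternated (variant-supporting) read
#'   counts per mutation site and spot.
#' @param D integer matrix, M x S, total read counts; `A <= D` elementwise.
#' @param coords integer matrix or data frame, S x 2, array grid positions
#'   of the spots (unit spacing); rows must be unique.
#' @param n_prior integer vector of S estimated cell counts per spot
#'   (e.g. from nuclei detection on the H&E image); all `>= 1`.
#' @return An object of class `spot_dataset` with elements `A`, `D`,
#'   `coords`, `n_prior`, `M`, `S`.
#' @export
spot_dataset <- function(A, D, coords, n_prior) {
  A <- as.matrix(A); D <- as.matrix(D)
  storage.mode(A) <- "integer"; storage.mode(D) <- "integer"
  if (!identical(dim(A), dim(D)))
    stop("A and D must have identical dimensions")
  if (any(D < 0)) stop("total read counts D must be non-negative")
  bad <- which(A > D | A < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    lab <- paste0("(", rownames(D)[bad[1, 1]] %||% bad[1, 1], ", ",
                  colnames(D)[bad[1, 2]] %||% bad[1, 2], ")")
    stop("invalid read counts: need 0 <= A <= D; first offending cell ", lab)
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || nrow(coords) != ncol(D))
    stop("coords must be an S x 2 matrix matching ncol(D)")
  if (anyDuplicated(coords))
    stop("spot coordinates must be unique")
  n_prior <- as.integer(round(n_prior))
  if (length(n_prior) != ncol(D))
    stop("n_prior must have one entry per spot")
  if (any(n_prior < 1)) stop("n_prior entries must all be >= 1")
  if (is.null(colnames(D))) colnames(D) <- paste0("spot", seq_len(ncol(D)))
  if (is.null(rownames(D))) rownames(D) <- paste0("mut", seq_len(nrow(D)))
  dimnames(A) <- dimnames(D)
  structure(
    list(A = A, D = D, coords = coords, n_prior = n_prior,
         M = nrow(D), S = ncol(D)),
    class = "spot_dataset")
}

#' Model hyperparameters
#'
#' @param zeta Beta shape numerator controlling the expected number of
#'   clones per spot; scalar (broadcast over spots) or length-S vector,
#'   strictly positive. The Beta prior on the presence probabilities is
#'   `Beta(zeta/K, 1)`, giving `K*zeta/(zeta + K)` expected clones per spot.
#' @param r,p shape and rate of the Gamma prior on the per-cell per-variant
#'   expected coverage; the prior mean is `r/p`.
#' @param lambda expected number of cells per spot (Poisson prior mean);
#'   scalar or length-S vector, strictly positive.
#' @param fixed_n if `TRUE`, per-spot cell counts are treated as known
#'   constants (the "fixed" model variant) and never updated.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(zeta, r, p, lambda, fixed_n = FALSE) {
  if (any(zeta <= 0)) stop("zeta must be positive")
  if (r <= 0 || p <= 0) stop("r and p must be positive")
  if (any(lambda <= 0)) stop("lambda must be positive")
  structure(
    list(zeta = as.numeric(zeta), r = r, p = p,
         lambda = as.numeric(lambda), fixed_n = isTRUE(fixed_n)),
    class = "hyperparams")
}

#' Latent model state
#'
#' Bundles one configuration of all latent variables. `H` is derived from
#' `G` by row normalization and is recomputed here rather than accepted
#' from the caller.
#'
#' @param Z S x K binary clone-presence indicators.
#' @param Pi S x K presence probabilities in (0, 1).
#' @param G S x K positive Gamma draws; `H = G / rowSums(G)`.
#' @param Phi M x K non-negative expected per-cell coverage values.
#' @param N length-S positive integer cell counts.
#' @return An object of class `latent_state` with the fields above plus `H`.
#' @export
latent_state <- function(Z, Pi, G, Phi, N) {
  Z <- as.matrix(Z); Pi <- as.matrix(Pi); G <- as.matrix(G)
  Phi <- as.matrix(Phi)
  if (!all(Z %in% c(0L, 1L))) stop("Z must be binary")
  if (any(G <= 0)) stop("G must be strictly positive")
  if (any(Phi < 0)) stop("Phi must be non-negative")
  N <- as.integer(round(N))
  if (any(N < 1)) stop("N must be >= 1")
  storage.mode(Z) <- "integer"
  structure(
    list(Z = Z, Pi = Pi, G = G, H = G / rowSums(G), Phi = Phi, N = N),
    class = "latent_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shape parameters of the Gamma prior on G for present clones: discretized
# prevalences floored at F0 so that clones absent from the bulk still have a
# proper density
g_shapes_present <- function(clones) pmax(clones$F_disc, clones$F0)

broadcast_spot <- function(x, S, what) {
  if (length(x) == 1) return(rep(as.numeric(x), S))
  if (length(x) != S) stop(what, " must be scalar or length S = ", S)
  as.numeric(x)
}
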