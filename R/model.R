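#' Discretize clone prevalences
#'
#' Maps bulk clone prevalences to Dirichlet/Gamma shape parameters by
#' rounding each value up to the upper bound of its 1/20-wide bin and
#' scaling by `l`:
#' \deqn{F'_k = l \cdot \lceil 20 F_k \rceil / 20.}
#' A prevalence of exactly 0 maps to 0; whether a zero shape is admissible
#' is decided by the caller (the model floors shapes at the
#' pseudo-frequency `F0`).
#'
#' @param F_prev numeric vector of prevalences in \[0, 1\].
#' @param l positive scaling factor (default 100).
#' @return Numeric vector of discretized, scaled prevalences.
#' @export
discretize_prevalence <- function(F_prev, l = 100) {
  if (l <= 0) stop("l must be positive")
  if (any(F_prev < 0 | F_prev > 1)) stop("prevalences must lie in [0, 1]")
  l * ceiling(20 * F_prev) / 20
}

#' Beta shape from an expected number of clones per spot
#'
#' The Beta(zeta_s/K, 1) prior over the presence probabilities implies
#' `K * (zeta_s/K) / (zeta_s/K + 1)` expected clones per spot. Inverting
#' for a target expectation `E` gives the shape parameter
#' \deqn{\zeta_s / K = E / (K - E).}
#'
#' @param E target expected number of clones per spot, `0 < E < K`.
#' @param K number of clones.
#' @return The scalar `zeta_s / K`.
#' @seealso [expected_clones_per_spot()] for the inverse map.
#' @export
zeta_over_K_from_expected_clones <- function(E, K) {
  if (E <= 0) stop("expected clones per spot must be positive")
  if (E >= K)
    stop("expected clones per spot must be < K: the Beta-Bernoulli prior ",
         "cannot reach an expectation of ", E, " with K = ", K)
  E / (K - E)
}

#' Expected number of clones per spot
#'
#' @param zeta_s Beta shape numerator (positive).
#' @param K number of clones (`>= 1`).
#' @return `K * zeta_s / (zeta_s + K)`, the expected number of present
#'   clones in a spot; inverse of [zeta_over_K_from_expected_clones()].
#' @export
expected_clones_per_spot <- function(zeta_s, K) {
  if (zeta_s <= 0) stop("zeta_s must be positive")
  if (K < 1) stop("K must be >= 1")
  K * zeta_s / (zeta_s + K)
}

#' Success probability of the alternated-read Binomial
#'
#' The expected fraction of variant-supporting reads at a site is the
#' clone-proportion- and expression-weighted zygosity,
#' \deqn{q = \sum_k H_{sk} \Phi_{ik} C_{ik} / \sum_k H_{sk} \Phi_{ik},}
#' which is invariant to overall expression level (homogeneous of degree 0
#' in `Phi_i`). When the denominator vanishes the site carries no reads in
#' expectation (reachable only with zero coverage) and the probability is
#' defined as 0 by convention.
#'
#' @param H_s length-K clone-proportion vector (simplex row).
#' @param Phi_i length-K non-negative expected per-cell coverage.
#' @param C_i length-K zygosity values in \[0, 1\].
#' @return Probability in \[0, 1\].
#' @export
alt_read_success_probability <- function(H_s, Phi_i, C_i) {
  den <- sum(H_s * Phi_i)
  if (den <= 0) {
    warning("degenerate site: sum_k H_sk * Phi_ik = 0; returning 0")
    return(0)
  }
  num <- sum(H_s * Phi_i * C_i)
  min(max(num / den, 0), 1)
}

#' Joint log-density of the generative model
#'
#' Sum of all prior log-density terms (presence probabilities, presence
#' indicators, Gamma draws behind the proportions, per-cell coverage, and
#' cell counts unless fixed) and both likelihood terms (Poisson total
#' reads, Binomial alternated reads). The cell-count prior is the Poisson
#' renormalized to support `N >= 1`.
#'
#' @param state a [latent_state()].
#' @param data a [spot_dataset()] (may have zero mutations/spots, in which
#'   case only prior terms contribute).
#' @param clones a [clone_set()].
#' @param hyper a [hyperparams()].
#' @return Scalar log-density; finite for any valid state.
#' @export
log_joint_density <- function(state, data, clones, hyper) {
  S <- nrow(state$Z); K <- ncol(state$Z)
  zetaK <- broadcast_spot(hyper$zeta, S, "zeta") / K
  lambda <- broadcast_spot(hyper$lambda, S, "lambda")
  shape1 <- g_shapes_present(clones)
  shape_mat <- ifelse(state$Z == 1,
                      matrix(shape1, S, K, byrow = TRUE), clones$F0)
  lp <- sum(stats::dbeta(state$Pi, zetaK, 1, log = TRUE)) +
    sum(stats::dbinom(state$Z, 1, state$Pi, log = TRUE)) +
    sum(stats::dgamma(state$G, shape = shape_mat, rate = 1, log = TRUE)) +
    sum(stats::dgamma(state$Phi, shape = hyper$r, rate = hyper$p, log = TRUE))
  if (!hyper$fixed_n)
    lp <- lp + sum(stats::dpois(state$N, lambda, log = TRUE) -
                     stats::ppois(0, lambda, lower.tail = FALSE, log.p = TRUE))
  M <- nrow(state$Phi)
  if (M > 0 && data$S > 0) {
    den <- state$Phi %*% t(state$H)                     # M x S
    num <- (state$Phi * clones$C) %*% t(state$H)
    mu <- sweep(den, 2, state$N, "*")
    q <- ifelse(den > 0, pmin(pmax(num / den, 0), 1), 0)
    lp <- lp + sum(stats::dpois(data$D, mu, log = TRUE)) +
      sum(stats::dbinom(data$A, data$D, q, log = TRUE))
  }
  lp
}

#' Log-odds of clone presence used by the indicator update
#'
#' Log-ratio of the two unnormalized masses of `Z_sk = 1` versus
#' `Z_sk = 0` given the current presence probability and Gamma draw. By
#' construction this equals the difference of [log_joint_density()]
#' evaluated at the two values of `Z_sk`.
#'
#' @inheritParams log_joint_density
#' @param s,k spot and clone index.
#' @return Scalar log-odds (may be infinite when `Pi` is 0 or 1).
#' @export
z_log_odds <- function(state, clones, hyper, s, k) {
  shape1 <- g_shapes_present(clones)[k]
  log(state$Pi[s, k]) - log1p(-state$Pi[s, k]) +
    stats::dgamma(state$G[s, k], shape1, rate = 1, log = TRUE) -
    stats::dgamma(state$G[s, k], clones$F0, rate = 1, log = TRUE)
}

#' Draw a dataset from the generative model
#'
#' Executes the model forward in topological order
#' (Pi, Z, G, H, Phi, N, D, A) and returns the latent state together with
#' the observed-data container. The returned pair is self-consistent:
#' `A <= D` elementwise and `H` is the row-normalization of `G`.
#'
#' @param clones a [clone_set()]; defines M and K.
#' @param hyper a [hyperparams()].
#' @param S number of spots.
#' @param coords optional S x 2 grid coordinates; defaults to a near-square
#'   grid with unit spacing.
#' @param seed optional integer seed.
#' @return List with elements `state` ([latent_state()]) and `data`
#'   ([spot_dataset()] whose `n_prior` is the true simulated cell count).
#' @export
sample_generative <- function(clones, hyper, S, coords = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- clones$M; K <- clones$K
  zetaK <- broadcast_spot(hyper$zeta, S, "zeta") / K
  lambda <- broadcast_spot(hyper$lambda, S, "lambda")
  shape1 <- g_shapes_present(clones)

  Pi <- matrix(rbeta(S * K, zetaK, 1), S, K)
  Z <- matrix(rbinom(S * K, 1, Pi), S, K)
  shape_mat <- ifelse(Z == 1, matrix(shape1, S, K, byrow = TRUE), clones$F0)
  G <- matrix(rgamma(S * K, shape = shape_mat, rate = 1), S, K)
  G[G <= 0] <- .Machine$double.xmin
  H <- G / rowSums(G)
  Phi <- matrix(rgamma(M * K, shape = hyper$r, rate = hyper$p), M, K)
  N <- rpois_positive(S, lambda)

  den <- Phi %*% t(H)                                   # M x S
  num <- (Phi * clones$C) %*% t(H)
  mu <- sweep(den, 2, N, "*")
  D <- matrix(rpois(M * S, mu), M, S)
  q <- ifelse(den > 0, pmin(pmax(num / den, 0), 1), 0)
  A <- matrix(rbinom(M * S, D, q), M, S)
  rownames(D) <- rownames(A) <- rownames(clones$C)

  if (is.null(coords)) coords <- default_grid(S)
  state <- latent_state(Z = Z, Pi = Pi, G = G, Phi = Phi, N = N)
  list(state = state,
       data = spot_dataset(A = A, D = D, coords = coords, n_prior = N))
}

# Poisson truncated to >= 1, drawn by inverse CDF on the truncated support
rpois_positive <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  u <- runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}

default_grid <- function(S) {
  ncols <- ceiling(sqrt(S))
  g <- cbind(x = rep(seq_len(ncols), length.out = S),
             y = rep(seq_len(ceiling(S / ncols)), each = ncols)[seq_len(S)])
  g
}
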